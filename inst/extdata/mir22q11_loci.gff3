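##gff-version 3
# miRNA primary transcripts of the typical 2.6 Mb 22q11.2 deletion region
# (hg19 coordinates; arms = mature species identified for the locus)
chr22	.	miRNA_primary_transcript	20020662	20020743	.	+	.	ID=miR-185;arms=5p,3p
chr22	.	miRNA_primary_transcript	21388465	21388561	.	+	.	ID=miR-649;arms=5p
chr22	.	miRNA_primary_transcript	20236657	20236734	.	+	.	ID=miR-1286;arms=5p
chr22	.	miRNA_primary_transcript	20073581	20073665	.	+	.	ID=miR-1306;arms=5p,3p
chr22	.	miRNA_primary_transcript	20073269	20073356	.	+	.	ID=miR-3618;arms=5p
chr22	.	miRNA_primary_transcript	19951276	19951357	.	+	.	ID=miR-4761;arms=5p,3p
chr22	.	miRNA_primary_transcript	20102209	20102274	.	+	.	ID=miR-6816;arms=5p,3p
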