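# Readers/writers: GFF3 miRNA annotation, GMT, edge lists, score tables,
# id maps, and the round-trip guarantees downstream modules rely on.

test_that("GFF3 reader recovers the 22q11.2-style annotation exactly", {
  path <- system.file("extdata", "mir22q11_loci.gff3", package = "mirgba")
  loci <- read_mirna_gff(path)
  expect_s3_class(loci, "mirna_loci")
  expect_equal(nrow(loci), 7L)
  m185 <- loci[loci$mirna_id == "miR-185", ]
  expect_equal(m185$chrom, "chr22")
  expect_equal(m185$start, 20020662)
  expect_equal(m185$end, 20020743)
  expect_equal(m185$arms, "5p,3p")
  # order preserved as in the file
  expect_equal(loci$mirna_id[1:2], c("miR-185", "miR-649"))
})

test_that("GFF3 reader rejects malformed records with line numbers", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\t.\tmiRNA_primary_transcript\t500\t400\t.\t+\t.\tID=x"),
             f)
  expect_error(read_mirna_gff(f), "line 2", class = "mirgba_parse_error")

  writeLines(c("##gff-version 3", "chr1\tonly\tthree"), f)
  expect_error(read_mirna_gff(f), "9 tab-separated",
               class = "mirgba_parse_error")

  writeLines(c("##gff-version 3",
               "chr1\t.\tmiRNA_primary_transcript\t1\t50\t.\t+\t.\tID=x",
               "chr1\t.\tmiRNA_primary_transcript\t9\t60\t.\t+\t.\tID=x"),
             f)
  expect_error(read_mirna_gff(f), "duplicate",
               class = "mirgba_validation_error")
})

test_that("GFF3 reader handles header-only files and ignores other types", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", f)
  expect_equal(nrow(read_mirna_gff(f)), 0L)
  writeLines(c("##gff-version 3",
               "chr1\t.\tgene\t1\t50\t.\t+\t.\tID=g1",
               "chr1\t.\tmiRNA_primary_transcript\t1\t50\t.\t+\t.\tID=m1"),
             f)
  expect_equal(read_mirna_gff(f)$mirna_id, "m1")
})

test_that("GMT reader deduplicates genes and validates structure", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines("S1\tdesc\tA\tB\tA", f)
  sets <- read_gmt(f)
  expect_setequal(sets[["S1"]], c("A", "B"))

  writeLines(c("S1\td\tA", "S1\td\tB"), f)
  expect_error(read_gmt(f), "duplicate", class = "mirgba_validation_error")

  writeLines("S1\tonlydesc", f)
  expect_error(read_gmt(f), ">= 3 fields", class = "mirgba_parse_error")

  lines <- sprintf("S%d\tdesc\t%s", 1:5,
                   vapply(1:5, function(i)
                     paste(sprintf("G%d_%d", i, 1:4), collapse = "\t"),
                     character(1)))
  writeLines(lines, f)
  # independent count: one set per well-formed line
  expect_length(read_gmt(f), length(lines))
})

test_that("edge list reader applies the weight/loop/duplicate rules", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b\tweight",
               "A\tB\t0.021", "B\tA\t0.03", "C\tC\t0.5", "A\tD\t0.019"), f)
  e <- suppressMessages(read_edge_list(f, weight_min = 0.02))
  # hand-trace: loop dropped, duplicate collapsed to max, A-D under cutoff
  expect_equal(nrow(e), 1L)
  expect_equal(e$gene_a, "A")
  expect_equal(e$gene_b, "B")
  expect_equal(e$weight, 0.03)
  expect_equal(attr(e, "nodes"), c("A", "B"))

  # weight exactly at the cutoff is kept (threshold is >=)
  writeLines(c("gene_a\tgene_b\tweight", "A\tB\t0.02"), f)
  expect_equal(nrow(read_edge_list(f, weight_min = 0.02)), 1L)

  # weight_min = 0 on loop-free input keeps everything
  writeLines(c("gene_a\tgene_b\tweight", "A\tB\t0.001", "B\tC\t0.5"), f)
  expect_equal(nrow(read_edge_list(f, weight_min = 0)), 2L)

  writeLines(c("gene_a\tgene_b\tweight", "A\tB\tnotanumber"), f)
  expect_error(read_edge_list(f), "non-numeric",
               class = "mirgba_parse_error")
})

test_that("edge filtering is idempotent", {
  f <- withr::local_tempfile(fileext = ".tsv")
  set.seed(42)
  g <- sprintf("N%02d", 1:20)
  df <- data.frame(gene_a = sample(g, 60, TRUE),
                   gene_b = sample(g, 60, TRUE),
                   weight = round(runif(60, 0, 0.1), 4))
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  e1 <- suppressMessages(read_edge_list(f, weight_min = 0.02))
  utils::write.table(e1, f, sep = "\t", quote = FALSE, row.names = FALSE)
  e2 <- suppressMessages(read_edge_list(f, weight_min = 0.02))
  expect_equal(as.data.frame(e1), as.data.frame(e2), ignore_attr = TRUE)
  expect_equal(attr(e1, "nodes"), attr(e2, "nodes"))
})

test_that("score tables round-trip, parse arms, and validate records", {
  st <- score_table("tool1", c("miR-185-5p", "miR-185-3p", "miR-649-5p"),
                    c("GRIN2A", "GRIN2A", "DLG1"), c(-0.5, -0.1, -0.9),
                    polarity = "smaller_is_stronger")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(st, f)
  back <- read_score_table(f, "tool1", polarity = "smaller_is_stronger")
  expect_equal(as.data.frame(back), as.data.frame(st))
  expect_equal(attr(back, "polarity"), "smaller_is_stronger")

  loci <- mirna_loci("miR-185", "chr22", 20020662, 20020743,
                     arms = "5p,3p")
  map <- resolve_mature_ids("miR-185-5p", loci)
  expect_equal(map$mirna_id, "miR-185")
  expect_equal(map$arm, "5p")

  expect_error(score_table("t", c("a-5p", "a-5p"), c("G1", "G1"), 1:2),
               "duplicate", class = "mirgba_validation_error")
  writeLines(c("mature_id\tgene\traw_score", "a-5p\tG1\t"), f)
  expect_error(read_score_table(f, "t"), "raw_score",
               class = "mirgba_parse_error")
})

test_that("every format round-trips through write-then-read", {
  d <- withr::local_tempdir()
  loci <- tiny_loci()
  write_mirna_gff(loci, file.path(d, "l.gff3"))
  expect_equal(as.data.frame(read_mirna_gff(file.path(d, "l.gff3"))),
               as.data.frame(loci))

  sets <- structure(list(S1 = c("A", "B"), S2 = c("B", "C", "D")),
                    descriptions = c(S1 = "one", S2 = "two"),
                    class = "gene_sets")
  write_gmt(sets, file.path(d, "s.gmt"))
  back <- read_gmt(file.path(d, "s.gmt"))
  expect_equal(unclass(back)[order(names(back))],
               unclass(sets)[order(names(sets))],
               ignore_attr = TRUE)

  ann <- relevance_annotation(c("A", "B"), c(TRUE, FALSE),
                              c(TRUE, TRUE), c(FALSE, FALSE))
  write_relevance(ann, file.path(d, "r.tsv"))
  expect_equal(as.data.frame(read_relevance(file.path(d, "r.tsv"))),
               as.data.frame(ann))
})

test_that("GMT parsing agrees with an independent reader", {
  skip_if_not_installed("fgsea")
  f <- withr::local_tempfile(fileext = ".gmt")
  set.seed(55)
  lines <- vapply(1:8, function(i)
    paste(c(sprintf("SET%d", i), "desc",
            sample(sprintf("G%03d", 1:200), sample(5:30, 1))),
          collapse = "\t"), character(1))
  writeLines(lines, f)
  mine <- read_gmt(f)
  ref <- fgsea::gmtPathways(f)
  expect_setequal(names(mine), names(ref))
  for (id in names(mine)) expect_setequal(mine[[id]], ref[[id]])
})

test_that("id maps drop and count unmapped genes at read time", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mature_id\tgene\traw_score",
               "m-5p\tSYMA\t1", "m-5p\tSYMB\t2", "m-5p\tSYMC\t3"), f)
  idm <- data.frame(from = c("SYMA", "SYMC"), to = c("1001", "1003"))
  st <- suppressMessages(
    read_score_table(f, "t", "larger_is_stronger", id_map = idm))
  expect_setequal(st$gene, c("1001", "1003"))
  expect_equal(attr(st, "n_unmapped"), 1L)
})

test_that("genomic interval constructor enforces its invariants", {
  expect_error(genomic_interval("chr1", 0, 10),
               class = "mirgba_validation_error")
  expect_error(genomic_interval("chr1", 10, 5),
               class = "mirgba_validation_error")
  expect_error(genomic_interval("", 1, 5),
               class = "mirgba_validation_error")
  r <- parse_region("chr22:18,876,416-21,465,674")
  expect_equal(r$start, 18876416)
  expect_equal(r$end, 21465674)
})
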