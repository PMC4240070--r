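# Independent oracles and tiny fixture builders shared across the suite.
# The oracles deliberately avoid the code paths they check.

# Right-tail Fisher p by direct hypergeometric enumeration with choose();
# independent of stats::phyper.
oracle_fisher_enum <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0L, c1 - (n - r1)); hi <- min(r1, c1)
  x <- lo:hi
  probs <- choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1)
  sum(probs[x >= a])
}

# Quadratic brute-force window counts: for each locus, loop over all loci.
oracle_window_counts <- function(loci, flank_bp, start_only = FALSE) {
  n <- nrow(loci)
  out <- integer(n)
  for (i in seq_len(n)) {
    ws <- max(1, loci$start[i] - flank_bp)
    we <- loci$start[i] + flank_bp
    cnt <- 0L
    for (j in seq_len(n)) {
      if (loci$chrom[j] != loci$chrom[i]) next
      inside <- if (start_only)
        loci$start[j] >= ws && loci$start[j] <= we
      else
        loci$start[j] >= ws && loci$end[j] <= we
      if (inside) cnt <- cnt + 1L
    }
    out[i] <- cnt
  }
  stats::setNames(out, loci$mirna_id)
}

# Per-gene neighbor recount for guilt-by-association scores, looping over
# the edge list one gene at a time.
oracle_gba_recount <- function(edges, candidates, brain, genes,
                               weights = c(penalty = -1, brain = 0.5,
                                           candidate = 2.5)) {
  rows <- lapply(genes, function(g) {
    nb <- c(edges$gene_b[edges$gene_a == g],
            edges$gene_a[edges$gene_b == g])
    if (!length(nb)) return(NULL)
    nc <- sum(nb %in% candidates)
    nbr <- sum(nb %in% brain & !(nb %in% candidates))
    no <- length(nb) - nc - nbr
    data.frame(gene = g, score = weights[["candidate"]] * nc +
                 weights[["brain"]] * nbr + weights[["penalty"]] * no,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

tiny_loci <- function() {
  mirna_loci(mirna_id = c("miR-A", "miR-B", "miR-C"),
             chrom = c("chr1", "chr1", "chr2"),
             start = c(100, 5000, 300), end = c(180, 5080, 360),
             strand = "+", arms = c("5p,3p", "5p", "3p"))
}

# A small synthetic spec that keeps unit tests fast; `...` overrides.
small_spec <- function(seed = 1L, ...) {
  args <- list(n_chromosomes = 2L, chrom_length_bp = 1e7,
               n_background_mirnas = 10L, cluster_size = 7L,
               cluster_span_bp = 2.6e6, n_genes = 600L, n_genesets = 12L,
               geneset_size_range = c(15L, 40L), targets_per_mirna = 120L,
               intertool_overlap = 0.7, n_candidates_gwas = 12L,
               n_candidates_cnv = 25L, shared_candidates = 1L,
               ppi_mean_degree = 5, core_density_boost = 6,
               n_core_partners = 15L, n_dysregulated = 5L, seed = seed)
  do.call(synth_spec, utils::modifyList(args, list(...)))
}

# Write all bundle paths into a named list run_pipeline() accepts.
bundle_paths <- function(dir) {
  list(gff = file.path(dir, "mirnas.gff3"),
       scores_tool1 = file.path(dir, "tool1_scores.tsv"),
       scores_tool2 = file.path(dir, "tool2_scores.tsv"),
       gmt = file.path(dir, "genesets.gmt"),
       edges = file.path(dir, "edges.tsv"),
       candidates_gwas = file.path(dir, "candidates_gwas.txt"),
       candidates_cnv = file.path(dir, "candidates_cnv.txt"),
       relevance = file.path(dir, "relevance.tsv"),
       dysregulated = file.path(dir, "dysregulated_mirnas.txt"))
}
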