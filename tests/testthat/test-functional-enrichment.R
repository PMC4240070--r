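# Contingency construction, the exact one-tailed test, FDR, consensus
# filtering, and the enrichment-map export.

test_that("gene-set size filter restricts to the universe, bounds inclusive", {
  sets <- structure(list(s10 = sprintf("G%02d", 1:10),
                         s15 = sprintf("G%02d", 1:15),
                         s20 = sprintf("G%02d", 1:20)),
                    class = "gene_sets")
  out <- filter_genesets(sets, min_size = 15, max_size = 15)
  expect_equal(names(out), "s15")
  # restriction to the universe happens before sizing
  out2 <- filter_genesets(sets, universe = sprintf("G%02d", 1:15),
                          min_size = 15, max_size = 900)
  expect_setequal(names(out2), c("s15", "s20"))
  expect_length(out2$s20, 15)
  expect_length(filter_genesets(structure(list(), class = "gene_sets"),
                                min_size = 15, max_size = 900), 0)
})

test_that("contingency cells follow the four-cell layout", {
  # hand-trace: E belongs to no gene-set and contributes to no cell
  cells <- build_contingency(targets_i = c("A", "B"),
                             background = c("A", "B", "C", "D", "E"),
                             gs_genes = c("A", "C"),
                             all_sets_union = c("A", "B", "C", "D"))
  expect_equal(cells, c(a = 1L, b = 1L, c = 1L, d = 1L))

  expect_equal(build_contingency(c("X", "Y"), c("X", "Y", "A"),
                                 c("A"), c("A"))[c("a", "b")],
               c(a = 0L, b = 0L))
  # gene-set equal to the union empties columns b and d
  cells2 <- build_contingency(c("A"), c("A", "B"), c("A", "B"),
                              c("A", "B"))
  expect_equal(unname(cells2[c("b", "d")]), c(0L, 0L))
  expect_error(build_contingency("A", character(), "A", "A"),
               class = "mirgba_computation_error")
})

test_that("one-tailed Fisher p equals exact enumeration on small tables", {
  expect_equal(fisher_one_tailed(c(a = 1, b = 1, c = 1, d = 1)), 5 / 6)
  expect_equal(fisher_one_tailed(c(a = 0, b = 3, c = 2, d = 9)), 1)
  expect_equal(fisher_one_tailed(c(a = 8, b = 2, c = 2, d = 8)),
               oracle_fisher_enum(8, 2, 2, 8))
  # spot-check random tables against the choose() enumeration oracle
  set.seed(17)
  for (i in 1:25) {
    tb <- sample.int(12, 4, replace = TRUE) - 1L
    expect_equal(
      fisher_one_tailed(c(a = tb[1], b = tb[2], c = tb[3], d = tb[4])),
      oracle_fisher_enum(tb[1], tb[2], tb[3], tb[4]),
      tolerance = 1e-12)
  }
})

test_that("BH adjustment reproduces the hand-computed step-up", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  # hand computation: sorted (0.002,0.005,0.03,0.04) -> step-up
  # (0.008, 0.01, 0.04, 0.04), mapped back to input order
  expect_equal(bh_fdr(c(0.005, 0.04, 0.03, 0.002)),
               c(0.01, 0.04, 0.04, 0.008))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(5)
  p <- runif(50)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-12))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "mirgba_validation_error")
})

test_that("consensus filter applies the 2-of-3 and short-list rules", {
  res <- data.frame(
    mirna_id = rep(c("m1", "m2", "m3"), each = 3),
    set_id = "S1", k_level = rep(c(200L, 400L, 800L), 3),
    a = 1L, b = 1L, c = 1L, d = 1L,
    p = c(0.005, 0.02, 0.009,   # 2 of 3 significant
          0.02, 0.02, 0.001,    # only 1 of 3
          0.009, 0.009, 0.02),  # 2 of 3
    fdr = 0.2)
  class(res) <- c("enrichment_results", "data.frame")
  out <- consensus_filter(res)
  expect_equal(stats::setNames(out$consensus, out$mirna_id)[c("m1", "m2",
                                                              "m3")],
               c(m1 = TRUE, m2 = FALSE, m3 = TRUE))
  expect_true(all(!out$short_list))

  short <- res[1, ]
  short$p <- 0.006
  expect_false(consensus_filter(short)$consensus)   # 0.005 rule
  short$p <- 0.005
  expect_true(consensus_filter(short)$consensus)
  expect_true(consensus_filter(short)$short_list)
})

test_that("set similarity combines Jaccard and overlap coefficients", {
  s <- set_similarity(c("A", "B", "C", "D"),
                      c("A", "B", "E", "F", "G", "H"))
  expect_equal(s[["jaccard"]], 2 / 8)
  expect_equal(s[["overlap"]], 2 / 4)
  expect_equal(s[["combined"]], 0.375)
  expect_equal(set_similarity(c("A"), c("A"))[["combined"]], 1)
  expect_equal(set_similarity(c("A"), c("B"))[["combined"]], 0)
})

test_that("enrichment-map export emits flagged nodes and thresholded edges", {
  cons <- data.frame(mirna_id = c("m1", "m2", "m1"),
                     set_id = c("S1", "S1", "S2"),
                     n_runs = 3L, n_nominal = 3L, min_p = 1e-4,
                     min_fdr = 0.1, short_list = FALSE,
                     consensus = c(TRUE, TRUE, TRUE),
                     fdr25 = c(TRUE, FALSE, FALSE))
  class(cons) <- c("consensus_results", "data.frame")
  sets <- list(S1 = c("A", "B", "C", "D"),
               S2 = c("A", "B", "E", "F", "G", "H"))
  map <- enrichment_map_export(cons, sets, similarity_threshold = 0.225)
  n1 <- map$nodes[map$nodes$set_id == "S1", ]
  expect_true(n1$multi_mirna)
  expect_true(n1$fdr25)
  expect_false(map$nodes$multi_mirna[map$nodes$set_id == "S2"])
  # combined 0.375 >= 0.225 -> edge kept
  expect_equal(nrow(map$edges), 1L)
  expect_equal(map$edges$combined, 0.375)
  # raising the threshold above the similarity removes the edge
  map2 <- enrichment_map_export(cons, sets, similarity_threshold = 0.5)
  expect_equal(nrow(map2$edges), 0L)
})

test_that("fraction of nominally significant pairs is controlled under the null", {
  # single-k runs on unplanted data: Fisher at p<=0.01 is (conservatively)
  # calibrated; rate stays within 3 binomial SDs of the nominal level
  spec <- synth_spec(n_chromosomes = 2L, chrom_length_bp = 1e7,
                     n_background_mirnas = 1L, cluster_size = 7L,
                     n_genes = 1500L, n_genesets = 80L,
                     geneset_size_range = c(20L, 80L),
                     targets_per_mirna = 400L, intertool_overlap = 0.8,
                     seed = 99L)
  loci <- gen_mirna_annotation(spec)
  sets <- gen_genesets(spec)
  scores <- gen_prediction_scores(spec, loci, sets)
  res <- integrate_scores(scores$tool1, scores$tool2, loci,
                          k_levels = 200L)
  enr <- enrich_targets(res$topk, sets,
                        background = sort(unique(res$targets$gene)))
  n <- nrow(enr)
  rate <- mean(enr$p <= 0.01)
  band <- 3 * sqrt(0.01 * 0.99 / n)
  expect_lte(rate, 0.01 + band)
})

test_that("short-list miRNAs contribute a single run", {
  spec <- small_spec(seed = 4)
  loci <- gen_mirna_annotation(spec)[1:3, ]
  sets <- gen_genesets(spec)
  scores <- gen_prediction_scores(spec, loci, sets)
  res <- integrate_scores(scores$tool1, scores$tool2, loci,
                          k_levels = c(200L, 400L, 800L))
  # 120 targets per tool, so every intersection is below the smallest k
  enr <- enrich_targets(res$topk, sets,
                        background = sort(unique(res$targets$gene)),
                        min_size = 5L, max_size = 900L)
  runs <- table(enr$mirna_id, enr$k_level)
  expect_true(all(rowSums(runs > 0) == 1))
  cons <- consensus_filter(enr)
  expect_true(all(cons$short_list))
})
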