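# Percentile transformation, arm collapsing, two-tool integration, and
# top-k list extraction.

test_that("percentile transform maps score strength to tail fractions", {
  # 100 distinct scores, larger stronger: strongest -> 0.01, the score at
  # the top-10% boundary -> exactly 0.10
  st <- score_table("t", sprintf("m-5p"), sprintf("G%03d", 1:100),
                    raw_score = 1:100, polarity = "larger_is_stronger")
  pct <- percentile_transform(st)
  expect_equal(pct$percentile[st$raw_score == 100], 0.01)
  expect_equal(pct$percentile[st$raw_score == 91], 0.10)
  expect_equal(pct$percentile[st$raw_score == 1], 1.0)

  # polarity flip: smallest raw is strongest
  st2 <- score_table("t", "m-5p", sprintf("G%03d", 1:100),
                     raw_score = 1:100, polarity = "smaller_is_stronger")
  pct2 <- percentile_transform(st2)
  expect_equal(pct2$percentile[st2$raw_score == 1], 0.01)

  # ties share the max-tie percentile; all-identical scores -> 1
  st3 <- score_table("t", "m-5p", c("A", "B", "C"), c(2, 2, 2),
                     polarity = "larger_is_stronger")
  expect_equal(percentile_transform(st3)$percentile, rep(1, 3))
})

test_that("percentiles lie in (0,1] and are monotone in strength", {
  set.seed(21)
  st <- score_table("t", "m-5p", sprintf("G%04d", 1:500),
                    raw_score = rnorm(500),
                    polarity = "larger_is_stronger")
  pct <- percentile_transform(st)
  expect_true(all(pct$percentile > 0 & pct$percentile <= 1))
  o <- order(-st$raw_score)
  expect_true(all(diff(pct$percentile[o]) >= 0))
  # permutation invariance: shuffled input gives the same per-gene values
  shuf <- sample.int(500)
  st_s <- score_table("t", "m-5p", st$gene[shuf], st$raw_score[shuf],
                      polarity = "larger_is_stronger")
  pct_s <- percentile_transform(st_s)
  expect_equal(pct_s$percentile[match(pct$gene, pct_s$gene)],
               pct$percentile)
})

test_that("arm collapsing averages dual-arm percentiles", {
  loci <- mirna_loci("miR-185", "chr22", 20020662, 20020743,
                     arms = "5p,3p")
  pct <- data.frame(mature_id = c("miR-185-5p", "miR-185-3p",
                                  "miR-185-5p"),
                    gene = c("G1", "G1", "G2"),
                    percentile = c(0.10, 0.30, 0.25))
  out <- collapse_arms(pct, loci)
  expect_equal(out$percentile[out$gene == "G1"], 0.20)
  expect_equal(out$percentile[out$gene == "G2"], 0.25)

  expect_error(collapse_arms(data.frame(mature_id = "miR-999-5p",
                                        gene = "G1", percentile = 0.5),
                             loci),
               "not resolvable", class = "mirgba_validation_error")
})

test_that("arm collapsing matches per-gene means on a dual-arm fixture", {
  set.seed(8)
  loci <- mirna_loci("miR-Z", "chr1", 100, 200, arms = "5p,3p")
  genes <- sprintf("G%02d", 1:10)
  pct <- data.frame(
    mature_id = c(rep("miR-Z-5p", 10), rep("miR-Z-3p", 6)),
    gene = c(genes, genes[1:6]),
    percentile = round(runif(16), 3))
  out <- collapse_arms(pct, loci)
  expected <- tapply(pct$percentile, pct$gene, mean)
  expect_equal(out$percentile, as.vector(expected[out$gene]))
})

test_that("tool integration keeps only genes predicted by both tools", {
  t1 <- data.frame(mirna_id = "m", gene = c("A", "B", "C"),
                   percentile = c(0.04, 0.5, 0.2))
  t2 <- data.frame(mirna_id = "m", gene = c("A", "C", "D"),
                   percentile = c(0.06, 0.1, 0.9))
  out <- integrate_tools(t1, t2)
  expect_setequal(out$gene, c("A", "C"))
  expect_equal(out$final_score[out$gene == "A"], 0.05)
  # ranking ascends in final score
  expect_equal(out$gene[out$rank == 1], "A")
})

test_that("integration is symmetric and matches a brute-force sort", {
  set.seed(31)
  genes <- sprintf("G%02d", 1:40)
  t1 <- data.frame(mirna_id = "m", gene = sample(genes, 30),
                   percentile = round(runif(30), 3))
  t2 <- data.frame(mirna_id = "m", gene = sample(genes, 30),
                   percentile = round(runif(30), 3))
  out <- integrate_tools(t1, t2)
  # brute force: intersect, average, order by (score, gene)
  common <- intersect(t1$gene, t2$gene)
  fs <- (t1$percentile[match(common, t1$gene)] +
           t2$percentile[match(common, t2$gene)]) / 2
  o <- order(fs, common)
  expect_equal(out$gene, common[o])
  expect_equal(out$final_score, fs[o])
  expect_equal(out$rank, seq_along(common))

  flipped <- integrate_tools(t2, t1)
  expect_equal(flipped$gene, out$gene)
  expect_equal(flipped$final_score, out$final_score)
  expect_equal(flipped$percentile_tool1, out$percentile_tool2)
})

test_that("miRNAs missing from either tool are excluded with a record", {
  t1 <- data.frame(mirna_id = c("m1", "m2"), gene = c("A", "B"),
                   percentile = c(0.1, 0.2))
  t2 <- data.frame(mirna_id = "m1", gene = "A", percentile = 0.3)
  out <- suppressMessages(integrate_tools(t1, t2,
                                          mirna_ids = c("m1", "m2")))
  expect_equal(attr(out, "excluded_mirnas"), "m2")
  expect_setequal(unique(out$mirna_id), "m1")
})

test_that("top-k lists are nested prefixes that tolerate short lists", {
  set.seed(13)
  n <- 149
  tg <- data.frame(mirna_id = "miR-1306", gene = sprintf("G%03d", 1:n),
                   percentile_tool1 = runif(n),
                   percentile_tool2 = runif(n))
  tg$final_score <- (tg$percentile_tool1 + tg$percentile_tool2) / 2
  tg <- tg[order(tg$final_score, tg$gene), ]
  tg$rank <- seq_len(n)
  tk <- topk(tg, c(200L, 400L, 800L))
  # fewer targets than every k: all lists hold the full 149
  expect_equal(lengths(tk$lists), c("200" = n, "400" = n, "800" = n))
  expect_equal(tk$n_targets, n)

  tk2 <- topk(tg, c(50L, 100L))
  expect_true(all(tk2$lists[["50"]] %in% tk2$lists[["100"]]))
  expect_equal(tk2$lists[["50"]], tg$gene[1:50])
  # reported mean equals the arithmetic mean of the slice
  expect_equal(tk2$mean_scores[["50"]], mean(tg$final_score[1:50]))
  expect_length(topk(tg, c(0L, 10L))$lists[["0"]], 0L)
  expect_error(topk(tg, c(100L, 100L)), class = "mirgba_validation_error")
})

test_that("the full integration chain runs on generated score tables", {
  spec <- small_spec(seed = 2)
  loci <- gen_mirna_annotation(spec)
  scores <- gen_prediction_scores(spec, loci)
  res <- integrate_scores(scores$tool1, scores$tool2, loci,
                          k_levels = c(20L, 50L))
  expect_s3_class(res$targets, "percentile_targets")
  expect_setequal(names(res$topk), loci$mirna_id)
  # every miRNA's ranks are a permutation of 1..N
  for (id in utils::head(names(res$topk), 3)) {
    sub <- res$targets[res$targets$mirna_id == id, ]
    expect_equal(sort(sub$rank), seq_len(nrow(sub)))
    expect_equal(sub$final_score,
                 (sub$percentile_tool1 + sub$percentile_tool2) / 2)
  }
})
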