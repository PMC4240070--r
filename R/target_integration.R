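# Two-tool target-score integration: percentile transformation over each
# tool's full prediction table, arm averaging, tool averaging, ranking,
# and top-k list extraction.

#' Percentile-transform one tool's prediction scores
#'
#' Scores are first oriented so that larger means stronger (per the table's
#' polarity), then each record's percentile is the fraction of records in
#' the WHOLE tool table — all putative targets of all miRNAs, both arms —
#' with strength at least as large. A score at the top-10% boundary thus
#' maps to exactly 0.10; smaller percentiles are stronger predictions.
#' Tied scores share a percentile (max-tie convention), and every value
#' lies in (0, 1].
#'
#' @param scores A [score_table()] (one tool).
#' @param polarity Overrides the table's stored polarity if given.
#' @return A data.frame `mature_id`, `gene`, `percentile`.
#' @export
percentile_transform <- function(scores, polarity = NULL) {
  if (!nrow(scores)) stop_validate("score table is empty")
  polarity <- polarity %||% attr(scores, "polarity")
  strength <- if (identical(polarity, "smaller_is_stronger"))
    -scores$raw_score else scores$raw_score
  n <- length(strength)
  # rank with max ties on descending strength = |{s' : s' >= s}|
  pct <- rank(-strength, ties.method = "max") / n
  data.frame(mature_id = scores$mature_id, gene = scores$gene,
             percentile = pct, stringsAsFactors = FALSE)
}

#' Resolve mature miRNA ids to (locus, arm)
#'
#' Mature ids are expected to carry a `-5p`/`-3p` suffix on the locus id
#' (e.g. `miR-185-5p` -> locus `miR-185`, arm `5p`). Ids without an arm
#' suffix resolve to the locus directly with arm `NA`.
#'
#' @param mature_ids Character vector of mature ids.
#' @param loci A [mirna_loci()] table the ids must resolve against.
#' @return A data.frame `mature_id`, `mirna_id`, `arm`.
#' @export
resolve_mature_ids <- function(mature_ids, loci) {
  ids <- unique(mature_ids)
  m <- regmatches(ids, regexec("^(.*)-(5p|3p)$", ids))
  mirna <- vapply(seq_along(ids), function(i) {
    if (length(m[[i]]) == 3L && m[[i]][2] %in% loci$mirna_id) m[[i]][2]
    else if (ids[i] %in% loci$mirna_id) ids[i]
    else NA_character_
  }, character(1))
  arm <- vapply(seq_along(ids), function(i) {
    if (length(m[[i]]) == 3L && m[[i]][2] %in% loci$mirna_id) m[[i]][3]
    else NA_character_
  }, character(1))
  if (anyNA(mirna))
    stop_validate("mature id(s) not resolvable to a locus: %s",
                  paste(utils::head(ids[is.na(mirna)], 5), collapse = ", "))
  data.frame(mature_id = ids, mirna_id = mirna, arm = arm,
             stringsAsFactors = FALSE)
}

#' Collapse arm-level percentiles to locus level
#'
#' Genes predicted for only one mature arm keep that arm's percentile;
#' genes predicted for both the -5p and -3p forms of the same locus get
#' the arithmetic mean of the two percentiles.
#'
#' @param percentiles Output of [percentile_transform()].
#' @param loci A [mirna_loci()] table used to resolve mature ids.
#' @return A data.frame `mirna_id`, `gene`, `percentile`.
#' @export
collapse_arms <- function(percentiles, loci) {
  map <- resolve_mature_ids(percentiles$mature_id, loci)
  mirna <- map$mirna_id[match(percentiles$mature_id, map$mature_id)]
  agg <- stats::aggregate(percentiles$percentile,
                          by = list(mirna_id = mirna,
                                    gene = percentiles$gene),
                          FUN = mean)
  names(agg)[3] <- "percentile"
  agg[order(agg$mirna_id, agg$gene), , drop = FALSE] -> agg
  rownames(agg) <- NULL
  agg
}

#' Integrate two tools' percentile tables into final per-miRNA rankings
#'
#' Conservative intersection strategy: a gene receives a final score only
#' if it is predicted by BOTH tools for that miRNA. The final score is the
#' mean of the two tool percentiles (smaller = stronger); genes are ranked
#' ascending by final score with ties broken by gene id. miRNAs listed in
#' `mirna_ids` but absent from either tool yield an empty ranking and a
#' logged exclusion.
#'
#' @param tool1,tool2 Locus-level percentile tables from [collapse_arms()].
#' @param mirna_ids Optional ids the result should cover (default: union
#'   of miRNAs seen in either tool).
#' @return A data.frame of class `percentile_targets` with columns
#'   `mirna_id`, `gene`, `percentile_tool1`, `percentile_tool2`,
#'   `final_score`, `rank`; attribute `excluded_mirnas`.
#' @export
integrate_tools <- function(tool1, tool2, mirna_ids = NULL) {
  mirna_ids <- mirna_ids %||% sort(unique(c(tool1$mirna_id, tool2$mirna_id)))
  merged <- merge(tool1, tool2, by = c("mirna_id", "gene"),
                  suffixes = c("_tool1", "_tool2"))
  merged$final_score <- (merged$percentile_tool1 +
                           merged$percentile_tool2) / 2
  excluded <- mirna_ids[!(mirna_ids %in% tool1$mirna_id &
                            mirna_ids %in% tool2$mirna_id)]
  for (id in excluded)
    mirgba_log("info",
               "miRNA %s lacks predictions from both tools; excluded", id)
  merged <- merged[merged$mirna_id %in% setdiff(mirna_ids, excluded), ,
                   drop = FALSE]
  o <- order(merged$mirna_id, merged$final_score, merged$gene)
  merged <- merged[o, , drop = FALSE]
  merged$rank <- stats::ave(merged$final_score, merged$mirna_id,
                            FUN = seq_along)
  merged$rank <- as.integer(merged$rank)
  rownames(merged) <- NULL
  structure(merged, excluded_mirnas = excluded,
            class = c("percentile_targets", "data.frame"))
}

#' Extract nested top-k target lists for one miRNA
#'
#' Prefix slices of the final ranking at each requested size. If fewer
#' targets exist than `k`, the list holds all of them (so a miRNA with 149
#' targets has identical lists at every level).
#'
#' @param targets Rows of a `percentile_targets` table for one miRNA.
#' @param k_levels Increasing integer list sizes (default 200, 400, 800).
#' @return An object of class `topk_lists`: `mirna_id`, `k_levels`,
#'   `lists` (named list of ordered gene vectors), `n_targets`,
#'   `mean_scores` (mean final score per list).
#' @export
topk <- function(targets, k_levels = c(200L, 400L, 800L)) {
  if (is.unsorted(k_levels, strictly = TRUE))
    stop_validate("k_levels must be strictly increasing")
  if (length(unique(targets$mirna_id)) > 1L)
    stop_validate("topk() expects targets of a single miRNA")
  targets <- targets[order(targets$rank), , drop = FALSE]
  lists <- lapply(k_levels, function(k)
    utils::head(targets$gene, max(k, 0L)))
  names(lists) <- as.character(k_levels)
  means <- vapply(k_levels, function(k)
    mean(utils::head(targets$final_score, max(k, 0L))), numeric(1))
  structure(list(mirna_id = if (nrow(targets)) targets$mirna_id[1] else NA,
                 k_levels = as.integer(k_levels), lists = lists,
                 n_targets = nrow(targets),
                 mean_scores = stats::setNames(means,
                                               as.character(k_levels))),
            class = "topk_lists")
}

#' Top-k lists for every miRNA in an integrated target table
#'
#' @param targets A `percentile_targets` table.
#' @param k_levels Increasing list sizes.
#' @return Named list of [topk()] objects, one per miRNA.
#' @export
topk_all <- function(targets, k_levels = c(200L, 400L, 800L)) {
  ids <- unique(targets$mirna_id)
  out <- lapply(ids, function(id)
    topk(targets[targets$mirna_id == id, , drop = FALSE], k_levels))
  stats::setNames(out, ids)
}

#' @export
print.topk_lists <- function(x, ...) {
  cat(sprintf("top-k target lists for %s (%d targets)\n",
              x$mirna_id, x$n_targets))
  for (k in names(x$lists))
    cat(sprintf("  k=%s: %d genes, mean final score %.4f\n",
                k, length(x$lists[[k]]), x$mean_scores[[k]]))
  invisible(x)
}

#' Run the full integration chain from two raw score tables
#'
#' Percentile-transforms each tool over its whole table, collapses arms,
#' intersects tools, ranks, and extracts top-k lists.
#'
#' @param scores1,scores2 [score_table()]s for the two tools.
#' @param loci A [mirna_loci()] table.
#' @param k_levels Increasing list sizes.
#' @return List with elements `targets` (`percentile_targets`) and
#'   `topk` (named list of `topk_lists`).
#' @export
integrate_scores <- function(scores1, scores2, loci,
                             k_levels = c(200L, 400L, 800L)) {
  t1 <- collapse_arms(percentile_transform(scores1), loci)
  t2 <- collapse_arms(percentile_transform(scores2), loci)
  targets <- integrate_tools(t1, t2, mirna_ids = loci$mirna_id)
  list(targets = targets, topk = topk_all(targets, k_levels))
}
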