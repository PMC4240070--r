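# Gene-set enrichment of miRNA target lists against the all-miRNA-target
# background: four-cell contingency tables, one-tailed Fisher's exact
# test, BH FDR per run, multi-threshold consensus filtering, and export
# of an enrichment-map similarity graph.

#' Size-filter a gene-set collection within an analysis universe
#'
#' Each set is first restricted to the analysis gene universe (the
#' background of all miRNA targets); sets whose restricted size falls
#' outside `[min_size, max_size]` (bounds inclusive) are dropped. Very
#' large sets are uninformative and very small ones are detrimental to
#' multiple-test correction, hence the conventional 15–900 defaults.
#'
#' @param sets A `gene_sets` collection.
#' @param universe Character vector of background genes; `NULL` keeps the
#'   sets as-is.
#' @param min_size,max_size Inclusive size bounds.
#' @return A filtered `gene_sets` collection (restricted to `universe`).
#' @export
filter_genesets <- function(sets, universe = NULL, min_size = 15L,
                            max_size = 900L) {
  restricted <- lapply(sets, function(g)
    if (is.null(universe)) g else intersect(g, universe))
  sizes <- lengths(restricted)
  keep <- sizes >= min_size & sizes <= max_size
  structure(restricted[keep],
            descriptions = attr(sets, "descriptions")[names(restricted)[keep]],
            class = "gene_sets")
}

#' Build the four-cell contingency table for one (miRNA, gene-set) pair
#'
#' Cells follow the target-vs-background layout: (a) targets of the miRNA
#' in the gene-set; (b) targets of the miRNA in at least one other
#' gene-set but not this one; (c) background targets of other miRNAs in
#' the gene-set; (d) background targets of other miRNAs in at least one
#' other gene-set but not this one. Genes belonging to no functional
#' gene-set contribute to no cell.
#'
#' @param targets_i Gene targets of the miRNA under test (subset of
#'   `background`).
#' @param background All-miRNA target universe.
#' @param gs_genes Genes of the set under test.
#' @param all_sets_union Union of genes over the whole (filtered)
#'   collection.
#' @return Named integer vector `c(a, b, c, d)`.
#' @export
build_contingency <- function(targets_i, background, gs_genes,
                              all_sets_union) {
  if (!length(background)) stop_compute("empty background universe")
  targets_i <- intersect(targets_i, background)
  rest <- setdiff(background, targets_i)
  other <- setdiff(all_sets_union, gs_genes)
  c(a = length(intersect(targets_i, gs_genes)),
    b = length(intersect(targets_i, other)),
    c = length(intersect(rest, gs_genes)),
    d = length(intersect(rest, other)))
}

#' One-tailed (right tail) Fisher's exact test
#'
#' Exact hypergeometric tail probability `P(X >= a)` with all margins
#' fixed — the enrichment-direction test. Shared by the enrichment and
#' overlap modules.
#'
#' @param cells Named vector or list with elements `a`, `b`, `c`, `d`.
#' @return The one-sided p-value.
#' @export
fisher_one_tailed <- function(cells) {
  a <- cells[["a"]]; b <- cells[["b"]]; cc <- cells[["c"]]; d <- cells[["d"]]
  if (any(c(a, b, cc, d) < 0)) stop_validate("negative contingency cell")
  # white balls = column 1 (gene-set members), draws = row 1 (targets)
  stats::phyper(a - 1, a + cc, b + d, a + b, lower.tail = FALSE)
}

#' Benjamini–Hochberg FDR adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement; input order
#' is preserved. Thin wrapper over [stats::p.adjust()] so a single routine
#' is used package-wide.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same order as input.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_validate("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Enrichment of every miRNA's top-k lists in a gene-set collection
#'
#' For each miRNA and each of its top-k lists (one run per k level; a
#' miRNA with fewer targets than the smallest k contributes a single run),
#' tests every gene-set with the one-tailed Fisher test and adjusts per
#' run by BH FDR.
#'
#' @param topk_by_mirna Named list of [topk()] objects.
#' @param sets `gene_sets` collection (will be size-filtered within the
#'   background universe).
#' @param background Character vector: union of all miRNAs' targets. If
#'   `NULL`, the union of all genes in `topk_by_mirna` is used.
#' @param min_size,max_size Gene-set size bounds (inclusive).
#' @return A data.frame of class `enrichment_results`: one row per
#'   (miRNA, set, k) with cells `a`–`d`, `p`, `fdr`, plus attributes
#'   `filtered_sets` and `background`.
#' @export
enrich_targets <- function(topk_by_mirna, sets, background = NULL,
                           min_size = 15L, max_size = 900L) {
  background <- background %||%
    sort(unique(unlist(lapply(topk_by_mirna, function(tk)
      tk$lists[[length(tk$lists)]]))))
  fsets <- filter_genesets(sets, universe = background,
                           min_size = min_size, max_size = max_size)
  if (!length(fsets)) {
    mirgba_log("warn", "no gene-sets survive the size filter")
  }
  union_genes <- unique(unlist(fsets, use.names = FALSE))
  rows <- list()
  for (id in names(topk_by_mirna)) {
    tk <- topk_by_mirna[[id]]
    ks <- .effective_runs(tk)
    for (k in ks) {
      targets_k <- intersect(tk$lists[[as.character(k)]], background)
      res <- lapply(names(fsets), function(sid) {
        cells <- build_contingency(targets_k, background, fsets[[sid]],
                                   union_genes)
        data.frame(mirna_id = id, set_id = sid, k_level = k,
                   a = cells[["a"]], b = cells[["b"]], c = cells[["c"]],
                   d = cells[["d"]], p = fisher_one_tailed(cells),
                   stringsAsFactors = FALSE)
      })
      run <- do.call(rbind, res)
      if (!is.null(run)) {
        run$fdr <- bh_fdr(run$p)
        rows[[length(rows) + 1L]] <- run
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(), set_id = character(),
               k_level = integer(), a = integer(), b = integer(),
               c = integer(), d = integer(), p = numeric(),
               fdr = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, filtered_sets = fsets, background = background,
            class = c("enrichment_results", "data.frame"))
}

# A miRNA whose whole target list is shorter than the smallest k level has
# one effective run (all its lists are identical).
.effective_runs <- function(tk) {
  if (tk$n_targets < min(tk$k_levels)) tk$k_levels[1] else tk$k_levels
}

#' Consensus significance filter across top-k runs
#'
#' A (miRNA, gene-set) pair is consensus-significant when nominally
#' significant (`p <= nominal_p`) in at least `min_runs` of its k-level
#' runs. miRNAs with a single run (target list shorter than the smallest
#' k) instead use the more stringent single-run threshold
#' `p <= short_list_p`.
#'
#' @param results An `enrichment_results` data.frame.
#' @param nominal_p Per-run nominal threshold (default 0.01).
#' @param short_list_p Single-run threshold for short-list miRNAs
#'   (default 0.005).
#' @param min_runs Minimum number of nominally significant runs
#'   (default 2).
#' @param fdr_border FDR level for the reporting flag (default 0.25).
#' @return A data.frame of class `consensus_results`, one row per
#'   (miRNA, set): `n_runs`, `n_nominal`, `min_p`, `min_fdr`,
#'   `short_list`, `consensus`, `fdr25`.
#' @export
consensus_filter <- function(results, nominal_p = 0.01,
                             short_list_p = 0.005, min_runs = 2L,
                             fdr_border = 0.25) {
  if (!nrow(results)) {
    out <- data.frame(mirna_id = character(), set_id = character(),
                      n_runs = integer(), n_nominal = integer(),
                      min_p = numeric(), min_fdr = numeric(),
                      short_list = logical(), consensus = logical(),
                      fdr25 = logical(), stringsAsFactors = FALSE)
    class(out) <- c("consensus_results", "data.frame")
    return(out)
  }
  key <- interaction(results$mirna_id, results$set_id, drop = TRUE)
  grp <- split(seq_len(nrow(results)), key)
  rows <- lapply(grp, function(ix) {
    p <- results$p[ix]
    short <- length(ix) == 1L
    data.frame(mirna_id = results$mirna_id[ix[1]],
               set_id = results$set_id[ix[1]],
               n_runs = length(ix),
               n_nominal = sum(p <= nominal_p),
               min_p = min(p), min_fdr = min(results$fdr[ix]),
               short_list = short,
               consensus = if (short) p[1] <= short_list_p
                           else sum(p <= nominal_p) >= min_runs,
               fdr25 = any(results$fdr[ix] <= fdr_border),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mirna_id, out$min_p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("consensus_results", "data.frame")
  out
}

#' Gene-set similarity (Jaccard, overlap, combined) for two sets
#'
#' The combined coefficient is the equal-weight mean of the Jaccard index
#' `|A∩B|/|A∪B|` and the overlap coefficient `|A∩B|/min(|A|,|B|)` — the
#' enrichment-map convention behind the usual 0.225 edge threshold.
#'
#' @param a,b Character gene vectors.
#' @param jaccard_weight Weight on the Jaccard term (overlap gets
#'   `1 - jaccard_weight`).
#' @return Named numeric `c(jaccard, overlap, combined)`.
#' @export
set_similarity <- function(a, b, jaccard_weight = 0.5) {
  i <- length(intersect(a, b))
  u <- length(union(a, b))
  jac <- if (u) i / u else 0
  ov <- if (min(length(a), length(b)) > 0) i / min(length(a), length(b))
        else 0
  c(jaccard = jac, overlap = ov,
    combined = jaccard_weight * jac + (1 - jaccard_weight) * ov)
}

#' Export consensus-significant gene-sets as an enrichment-map graph
#'
#' Nodes are the gene-sets passing the consensus filter for at least one
#' miRNA, annotated with size, the miRNAs hitting them, a multi-miRNA
#' flag, and whether any run reached the FDR reporting border. Edges join
#' set pairs whose combined similarity coefficient reaches the threshold.
#'
#' @param consensus A `consensus_results` data.frame.
#' @param sets The filtered `gene_sets` the results refer to.
#' @param similarity_threshold Minimum combined coefficient for an edge
#'   (default 0.225).
#' @param jaccard_weight Passed to [set_similarity()].
#' @return List with data.frames `nodes` (`set_id`, `size`, `mirnas`,
#'   `n_mirnas`, `multi_mirna`, `fdr25`) and `edges` (`set_a`, `set_b`,
#'   `jaccard`, `overlap`, `combined`).
#' @export
enrichment_map_export <- function(consensus, sets,
                                  similarity_threshold = 0.225,
                                  jaccard_weight = 0.5) {
  hits <- consensus[consensus$consensus, , drop = FALSE]
  ids <- sort(unique(hits$set_id))
  nodes <- do.call(rbind, lapply(ids, function(sid) {
    h <- hits[hits$set_id == sid, , drop = FALSE]
    data.frame(set_id = sid, size = length(sets[[sid]]),
               mirnas = paste(sort(unique(h$mirna_id)), collapse = ","),
               n_mirnas = length(unique(h$mirna_id)),
               multi_mirna = length(unique(h$mirna_id)) > 1L,
               fdr25 = any(h$fdr25), stringsAsFactors = FALSE)
  })) %||% data.frame(set_id = character(), size = integer(),
                      mirnas = character(), n_mirnas = integer(),
                      multi_mirna = logical(), fdr25 = logical())
  edges <- data.frame(set_a = character(), set_b = character(),
                      jaccard = numeric(), overlap = numeric(),
                      combined = numeric(), stringsAsFactors = FALSE)
  if (length(ids) > 1L) {
    pairs <- utils::combn(ids, 2)
    rows <- lapply(seq_len(ncol(pairs)), function(j) {
      s <- set_similarity(sets[[pairs[1, j]]], sets[[pairs[2, j]]],
                          jaccard_weight)
      data.frame(set_a = pairs[1, j], set_b = pairs[2, j],
                 jaccard = s[["jaccard"]], overlap = s[["overlap"]],
                 combined = s[["combined"]], stringsAsFactors = FALSE)
    })
    edges <- do.call(rbind, rows)
    edges <- edges[edges$combined >= similarity_threshold, , drop = FALSE]
    rownames(edges) <- NULL
  }
  list(nodes = nodes, edges = edges)
}
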