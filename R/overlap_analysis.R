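# Mechanism target sets (region-miRNA union; microprocessor-dysregulation
# set) and their overlap with the disease network by one-sided Fisher's
# exact test.

#' Union of the region miRNAs' top-k targets
#'
#' @param topk_by_mirna Named list of [topk()] objects for the region
#'   miRNAs.
#' @param k List level to take (default 200).
#' @return An object of class `mechanism_set`: `label`, `genes`,
#'   `provenance` (data.frame gene -> contributing miRNAs).
#' @export
region_target_union <- function(topk_by_mirna, k = 200L) {
  kc <- as.character(k)
  prov <- list()
  for (id in names(topk_by_mirna)) {
    tk <- topk_by_mirna[[id]]
    lst <- tk$lists[[kc]] %||% tk$lists[[length(tk$lists)]]
    for (g in lst) prov[[g]] <- c(prov[[g]], id)
  }
  genes <- sort(names(prov))
  provenance <- data.frame(
    gene = genes,
    mirnas = vapply(genes, function(g)
      paste(sort(unique(prov[[g]])), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  structure(list(label = "region_mirna", genes = genes,
                 provenance = provenance),
            class = "mechanism_set")
}

#' Target set of the microprocessor-dysregulation mechanism
#'
#' Genes appearing in the top-k lists of at least `min_mirnas` of the
#' dysregulated miRNAs, minus the genes already targeted by the region
#' miRNAs (so the two mechanism sets are disjoint).
#'
#' @param topk_all_mirnas Named list of [topk()] objects covering the
#'   genome-wide miRNAs.
#' @param dysregulated Character vector of dysregulated miRNA ids; every
#'   id must be present in `topk_all_mirnas`.
#' @param min_mirnas Minimum number of dysregulated miRNAs whose lists
#'   must contain the gene (default 2).
#' @param exclude A `mechanism_set` (or character vector) of genes to
#'   remove, typically the region-miRNA target union.
#' @param k List level (default 200).
#' @return A `mechanism_set` with label `"dgcr8"`.
#' @export
dgcr8_set <- function(topk_all_mirnas, dysregulated, min_mirnas = 2L,
                      exclude = character(), k = 200L) {
  unknown <- setdiff(dysregulated, names(topk_all_mirnas))
  if (length(unknown))
    stop_validate("unknown dysregulated miRNA id(s): %s",
                  paste(unknown, collapse = ", "))
  kc <- as.character(k)
  prov <- list()
  for (id in dysregulated) {
    tk <- topk_all_mirnas[[id]]
    lst <- tk$lists[[kc]] %||% tk$lists[[length(tk$lists)]]
    for (g in lst) prov[[g]] <- c(prov[[g]], id)
  }
  counts <- vapply(prov, function(x) length(unique(x)), integer(1))
  genes <- names(counts)[counts >= min_mirnas]
  excl <- if (inherits(exclude, "mechanism_set")) exclude$genes
          else as.character(exclude)
  genes <- sort(setdiff(genes, excl))
  provenance <- data.frame(
    gene = genes,
    mirnas = vapply(genes, function(g)
      paste(sort(unique(prov[[g]])), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  structure(list(label = "dgcr8", genes = genes, provenance = provenance),
            class = "mechanism_set")
}

#' @export
print.mechanism_set <- function(x, ...) {
  cat(sprintf("mechanism target set '%s': %d genes\n", x$label,
              length(x$genes)))
  invisible(x)
}

#' One-sided overlap test of a mechanism set against the network
#'
#' 2x2 layout: a = mechanism genes in the network, b = mechanism genes
#' outside, c = network genes outside the mechanism, d = universe genes in
#' neither. Mechanism genes outside the universe are dropped (and
#' counted) before testing. The p-value is the right-tail Fisher test
#' (same routine as the enrichment module); the odds ratio is the sample
#' cross-product estimate, with the conditional MLE also reported.
#'
#' @param mechanism A `mechanism_set` or character gene vector.
#' @param network_genes Genes of the disease network (must be a subset of
#'   `universe`).
#' @param universe Background gene universe, conventionally all genes of
#'   the weight-filtered interaction network.
#' @return An object of class `overlap_test`: the four cells, `p`,
#'   `or_sample`, `or_cmle`, and bookkeeping counts.
#' @export
overlap_test <- function(mechanism, network_genes, universe) {
  mech_label <- if (inherits(mechanism, "mechanism_set")) mechanism$label
                else "custom"
  mech <- if (inherits(mechanism, "mechanism_set")) mechanism$genes
          else unique(as.character(mechanism))
  network_genes <- unique(network_genes)
  universe <- unique(universe)
  if (length(setdiff(network_genes, universe)))
    stop_validate("network genes must be contained in the universe")
  n_outside <- length(setdiff(mech, universe))
  if (n_outside)
    mirgba_log("info", "%d mechanism gene(s) outside the universe dropped",
               n_outside)
  mech <- intersect(mech, universe)
  a <- length(intersect(mech, network_genes))
  b <- length(setdiff(mech, network_genes))
  cc <- length(setdiff(network_genes, mech))
  d <- length(universe) - a - b - cc
  cells <- c(a = a, b = b, c = cc, d = d)
  p <- fisher_one_tailed(cells)
  or_sample <- if (b * cc == 0) Inf else (a * d) / (b * cc)
  or_cmle <- unname(stats::fisher.test(matrix(c(a, cc, b, d), 2),
                                       alternative = "greater")$estimate)
  structure(list(mechanism = mech_label, cells = cells, p = p,
                 or_sample = or_sample, or_cmle = or_cmle,
                 n_in_network = a, n_mechanism = a + b,
                 n_network = length(network_genes),
                 n_universe = length(universe),
                 n_dropped_outside_universe = n_outside),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("overlap of mechanism '%s' with the network\n", x$mechanism))
  cat(sprintf("  %d of %d mechanism genes in the %d-gene network (universe %d)\n",
              x$n_in_network, x$n_mechanism, x$n_network, x$n_universe))
  cat(sprintf("  one-sided Fisher p = %.4g, odds ratio = %.2f (CMLE %.2f)\n",
              x$p, x$or_sample, x$or_cmle))
  invisible(x)
}

#' Annotate a ranked gene list with mechanism membership
#'
#' @param ranking Ordered gene vector (from [rank_by_score()]).
#' @param region_set,dgcr8_set The two `mechanism_set`s (or character
#'   vectors).
#' @param top_n Number of top genes to annotate (default 50).
#' @return A data.frame `gene`, `rank`, `region_mirna_target`,
#'   `dgcr8_target`, `any_mechanism`, with attributes `n_hit` and
#'   `fraction_hit` over the `top_n` genes.
#' @export
annotate_top_genes <- function(ranking, region_set, dgcr8_set,
                               top_n = 50L) {
  reg <- if (inherits(region_set, "mechanism_set")) region_set$genes
         else as.character(region_set)
  dg <- if (inherits(dgcr8_set, "mechanism_set")) dgcr8_set$genes
        else as.character(dgcr8_set)
  top <- utils::head(ranking, top_n)
  out <- data.frame(gene = top, rank = seq_along(top),
                    region_mirna_target = top %in% reg,
                    dgcr8_target = top %in% dg,
                    stringsAsFactors = FALSE)
  out$any_mechanism <- out$region_mirna_target | out$dgcr8_target
  structure(out, n_hit = sum(out$any_mechanism),
            fraction_hit = if (nrow(out)) mean(out$any_mechanism) else 0)
}
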