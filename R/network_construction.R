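# Disease gene network construction: candidate list union, relevance
# filtering, additive guilt-by-association scoring over first-degree
# interactions, retention, and induction of the final network.

#' Merge two candidate gene lists
#'
#' @param list_a,list_b Character gene vectors (e.g. GWAS-derived and rare
#'   CNV-derived candidates).
#' @return Character union, with attributes `n_a`, `n_b`, `n_shared`,
#'   `n_union`.
#' @export
merge_candidates <- function(list_a, list_b) {
  a <- unique(list_a); b <- unique(list_b)
  u <- union(a, b)
  mirgba_log("info", "candidate lists: %d + %d, %d shared, %d union",
             length(a), length(b), length(intersect(a, b)), length(u))
  structure(u, n_a = length(a), n_b = length(b),
            n_shared = length(intersect(a, b)), n_union = length(u))
}

#' Filter genes by the number of brain-relevance criteria met
#'
#' Genes missing from the annotation meet 0 criteria (logged).
#'
#' @param genes Character vector to filter.
#' @param annotations A [relevance_annotation()] table.
#' @param min_criteria Minimum criteria required (candidates conventionally
#'   need >= 1, other genes >= 2).
#' @return Character vector of retained genes.
#' @export
apply_relevance_filter <- function(genes, annotations, min_criteria = 1L) {
  genes <- unique(genes)
  met <- annotations$criteria_met[match(genes, annotations$gene)]
  missing <- is.na(met)
  if (any(missing))
    mirgba_log("info", "%d gene(s) without relevance annotation (0 criteria)",
               sum(missing))
  met[missing] <- 0L
  genes[met >= min_criteria]
}

#' Additive guilt-by-association scores over first-degree interactions
#'
#' Each gene to score receives, per neighbor in the weight-filtered
#' interaction network: `score_candidate` (+2.5) if the neighbor is a
#' disease candidate, `score_brain` (+0.5) if the neighbor is labeled
#' relevant to brain function (candidates excluded), and `score_penalty`
#' (−1) otherwise. Genes with no network neighbors are unscored (absent
#' from the result).
#'
#' @param edges An `interaction_edges` data.frame (already weight
#'   filtered).
#' @param candidates Candidate gene set.
#' @param brain_genes Brain-relevant gene set; must be disjoint from
#'   `candidates`.
#' @param genes Genes to score (default `brain_genes`).
#' @param weights Named numeric `c(penalty, brain, candidate)`.
#' @return A data.frame of class `gba_scores`: `gene`,
#'   `n_candidate_neighbors`, `n_brain_neighbors`, `n_other_neighbors`,
#'   `score`, sorted by decreasing score.
#' @export
gba_score <- function(edges, candidates, brain_genes,
                      genes = brain_genes,
                      weights = c(penalty = -1, brain = 0.5,
                                  candidate = 2.5)) {
  if (length(intersect(candidates, brain_genes)))
    stop_validate("candidate and brain-relevant sets must be disjoint")
  long <- data.frame(gene = c(edges$gene_a, edges$gene_b),
                     neighbor = c(edges$gene_b, edges$gene_a),
                     stringsAsFactors = FALSE)
  long <- long[long$gene %in% genes, , drop = FALSE]
  if (!nrow(long)) {
    out <- data.frame(gene = character(), n_candidate_neighbors = integer(),
                      n_brain_neighbors = integer(),
                      n_other_neighbors = integer(), score = numeric(),
                      stringsAsFactors = FALSE)
    class(out) <- c("gba_scores", "data.frame")
    return(out)
  }
  cls <- ifelse(long$neighbor %in% candidates, "candidate",
                ifelse(long$neighbor %in% brain_genes, "brain", "other"))
  tab <- table(long$gene, factor(cls, levels = c("candidate", "brain",
                                                 "other")))
  out <- data.frame(gene = rownames(tab),
                    n_candidate_neighbors = as.integer(tab[, "candidate"]),
                    n_brain_neighbors = as.integer(tab[, "brain"]),
                    n_other_neighbors = as.integer(tab[, "other"]),
                    stringsAsFactors = FALSE)
  out$score <- weights[["candidate"]] * out$n_candidate_neighbors +
    weights[["brain"]] * out$n_brain_neighbors +
    weights[["penalty"]] * out$n_other_neighbors
  out <- out[order(-out$score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gba_scores", "data.frame")
  out
}

#' Build the final disease network
#'
#' Nodes are the filtered candidates plus brain-relevant genes whose
#' guilt-by-association score reaches `retain_min` ("partners"); edges are
#' the interaction edges with both endpoints among those nodes; nodes left
#' without any surviving edge are dropped. Candidates are eligible
#' regardless of score; partners must pass retention.
#'
#' @param edges Weight-filtered `interaction_edges`.
#' @param candidates Filtered candidate gene set.
#' @param scores A `gba_scores` table for the brain-relevant genes.
#' @param retain_min Minimum partner score (inclusive; default 1.5).
#' @param candidate_scores Optional `gba_scores` for the candidates
#'   themselves (used for ranking; computed with the same additive rule).
#' @return An object of class `disease_network`: `nodes` data.frame
#'   (`gene`, `role`, `score`), `edges` data.frame, and stage counts.
#' @export
build_network <- function(edges, candidates, scores, retain_min = 1.5,
                          candidate_scores = NULL) {
  partners <- scores$gene[scores$score >= retain_min]
  eligible <- union(candidates, partners)
  keep <- edges$gene_a %in% eligible & edges$gene_b %in% eligible
  net_edges <- edges[keep, , drop = FALSE]
  rownames(net_edges) <- NULL
  connected <- sort(unique(c(net_edges$gene_a, net_edges$gene_b)))
  node_genes <- connected
  role <- ifelse(node_genes %in% candidates, "candidate", "partner")
  score_lookup <- stats::setNames(scores$score, scores$gene)
  if (!is.null(candidate_scores))
    score_lookup <- c(score_lookup,
                      stats::setNames(candidate_scores$score,
                                      candidate_scores$gene))
  nodes <- data.frame(gene = node_genes, role = role,
                      score = unname(score_lookup[node_genes]),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes,
                 edges = net_edges[, c("gene_a", "gene_b", "weight")],
                 counts = list(
                   n_candidates_in = length(unique(candidates)),
                   n_candidates_kept = sum(role == "candidate"),
                   n_partners_scored = nrow(scores),
                   n_partners_retained = length(partners),
                   n_partners_kept = sum(role == "partner"),
                   n_nodes = nrow(nodes), n_edges = nrow(net_edges)),
                 retain_min = retain_min),
            class = "disease_network")
}

#' @export
print.disease_network <- function(x, ...) {
  cat("disease gene network\n")
  cat(sprintf("  nodes: %d (%d of %d candidates, %d of %d retained partners)\n",
              x$counts$n_nodes, x$counts$n_candidates_kept,
              x$counts$n_candidates_in, x$counts$n_partners_kept,
              x$counts$n_partners_retained))
  cat(sprintf("  edges: %d (partner retention score >= %.2f)\n",
              x$counts$n_edges, x$retain_min))
  invisible(x)
}

#' Rank network genes by guilt-by-association score
#'
#' Descending score; ties broken by gene id so the ranking is
#' deterministic.
#'
#' @param network A `disease_network`.
#' @param top_n Number of genes to return (default all).
#' @return Character vector of gene ids in rank order.
#' @export
rank_by_score <- function(network, top_n = nrow(network$nodes)) {
  if (top_n <= 0) stop_validate("top_n must be positive")
  nodes <- network$nodes
  o <- order(-nodes$score, nodes$gene)
  utils::head(nodes$gene[o], top_n)
}

#' Full network-construction chain
#'
#' Merges the two candidate lists, applies the relevance filters
#' (>= `candidate_criteria_min` of 3 for candidates,
#' >= `partner_criteria_min` of 3 for other genes), scores brain-relevant
#' genes over the weight-filtered interaction network, and induces the
#' final network. Scoring uses the full filtered interaction network, not
#' the final network (scores are computed before construction).
#'
#' @param edges Weight-filtered `interaction_edges`.
#' @param candidates_a,candidates_b The two candidate lists.
#' @param annotations A [relevance_annotation()] table.
#' @param candidate_criteria_min,partner_criteria_min Criteria thresholds.
#' @param weights Additive scoring weights, as in [gba_score()].
#' @param retain_min Partner retention threshold.
#' @return A `disease_network`, with the intermediate sets attached in
#'   `$inputs`.
#' @export
construct_disease_network <- function(edges, candidates_a, candidates_b,
                                      annotations,
                                      candidate_criteria_min = 1L,
                                      partner_criteria_min = 2L,
                                      weights = c(penalty = -1, brain = 0.5,
                                                  candidate = 2.5),
                                      retain_min = 1.5) {
  merged <- merge_candidates(candidates_a, candidates_b)
  candidates <- apply_relevance_filter(merged, annotations,
                                       candidate_criteria_min)
  all_nodes <- attr(edges, "nodes") %||%
    unique(c(edges$gene_a, edges$gene_b))
  brain_pool <- setdiff(annotations$gene, candidates)
  brain_genes <- apply_relevance_filter(brain_pool, annotations,
                                        partner_criteria_min)
  scores <- gba_score(edges, candidates, brain_genes, weights = weights)
  cand_scores <- gba_score(edges, candidates, brain_genes,
                           genes = candidates, weights = weights)
  net <- build_network(edges, candidates, scores, retain_min = retain_min,
                       candidate_scores = cand_scores)
  net$counts$n_candidates_merged <- length(merged)
  net$counts$n_brain_genes <- length(brain_genes)
  net$inputs <- list(candidates = candidates, brain_genes = brain_genes,
                     scores = scores, candidate_scores = cand_scores)
  net
}
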