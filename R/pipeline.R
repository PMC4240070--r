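# End-to-end orchestration: one config object, stages run in dependency
# order (density and target integration feed enrichment; candidates and
# edges feed the network; targets and network feed the overlap tests),
# and a manifest of every count at every filter step.

#' Pipeline configuration
#'
#' Houses every numeric threshold of the analysis. Defaults are the
#' conventional values: a 2.6 Mb density window (1.3 Mb flank), top
#' 200/400/800 target lists, 15–900 gene-set sizes, nominal p 0.01 with
#' 0.005 for single-run (short-list) miRNAs and a 2-of-3 consensus, FDR
#' reporting border 0.25, enrichment-map similarity threshold 0.225,
#' interaction weight cutoff 0.02, additive scoring weights
#' (−1, +0.5, +2.5) with retention at 1.5, and relevance thresholds of
#' 1-of-3 for candidates and 2-of-3 for other genes.
#'
#' @param region Query region: a [genomic_interval()] or a
#'   `"chr:start-end"` string (`NULL` to skip the density stage only if
#'   no region is known).
#' @param window_flank_bp Density window flank in bp.
#' @param topk_levels Strictly increasing target list sizes.
#' @param geneset_min,geneset_max Inclusive gene-set size bounds.
#' @param nominal_p,short_list_p,consensus_min_runs Consensus filter
#'   parameters.
#' @param fdr_border FDR reporting border.
#' @param similarity_threshold Enrichment-map combined-coefficient edge
#'   threshold.
#' @param edge_weight_min Interaction weight cutoff (inclusive).
#' @param score_penalty,score_brain,score_candidate Additive
#'   guilt-by-association weights.
#' @param retain_score_min Partner retention threshold (inclusive).
#' @param candidate_criteria_min,partner_criteria_min Relevance criteria
#'   thresholds.
#' @param overlap_k Top-k level used for the mechanism target sets.
#' @param min_dysregulated_mirnas Minimum dysregulated miRNAs whose lists
#'   must share a gene for the microprocessor mechanism set.
#' @param top_n_genes Size of the annotated top-gene ranking.
#' @param rng_seed Seed recorded in the manifest.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(region = NULL, window_flank_bp = 1.3e6,
                            topk_levels = c(200L, 400L, 800L),
                            geneset_min = 15L, geneset_max = 900L,
                            nominal_p = 0.01, short_list_p = 0.005,
                            consensus_min_runs = 2L, fdr_border = 0.25,
                            similarity_threshold = 0.225,
                            edge_weight_min = 0.02, score_penalty = -1,
                            score_brain = 0.5, score_candidate = 2.5,
                            retain_score_min = 1.5,
                            candidate_criteria_min = 1L,
                            partner_criteria_min = 2L, overlap_k = 200L,
                            min_dysregulated_mirnas = 2L,
                            top_n_genes = 50L, rng_seed = 1L) {
  if (is.character(region)) region <- parse_region(region)
  cfg <- list(region = region, window_flank_bp = window_flank_bp,
              topk_levels = as.integer(topk_levels),
              geneset_min = as.integer(geneset_min),
              geneset_max = as.integer(geneset_max),
              nominal_p = nominal_p, short_list_p = short_list_p,
              consensus_min_runs = as.integer(consensus_min_runs),
              fdr_border = fdr_border,
              similarity_threshold = similarity_threshold,
              edge_weight_min = edge_weight_min,
              score_penalty = score_penalty, score_brain = score_brain,
              score_candidate = score_candidate,
              retain_score_min = retain_score_min,
              candidate_criteria_min = as.integer(candidate_criteria_min),
              partner_criteria_min = as.integer(partner_criteria_min),
              overlap_k = as.integer(overlap_k),
              min_dysregulated_mirnas = as.integer(min_dysregulated_mirnas),
              top_n_genes = as.integer(top_n_genes),
              rng_seed = as.integer(rng_seed))
  nums <- unlist(cfg[setdiff(names(cfg), "region")])
  if (any(!is.finite(nums)))
    stop_config("all configuration thresholds must be finite")
  if (is.unsorted(cfg$topk_levels, strictly = TRUE))
    stop_config("topk_levels must be strictly increasing")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are an
#' error.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_parse("file not found: %s", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop_config("unknown configuration key(s): %s",
                paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(
      sprintf("stage '%s': %s", name, conditionMessage(e)),
      class = c("mirgba_stage_error", "mirgba_error")))
  })
}

#' Run the full pipeline
#'
#' Executes annotation, density, target integration, functional
#' enrichment, network construction and overlap testing in dependency
#' order, writes all stage outputs as TSV/JSON under `out_dir` (when
#' given), and returns every stage result plus a run manifest of counts.
#' Identical inputs and configuration give identical outputs.
#'
#' @param paths Named list of input paths: `gff`, `scores_tool1`,
#'   `scores_tool2`, `gmt`, `edges`, `candidates_gwas`, `candidates_cnv`,
#'   `relevance`, `dysregulated`; optional `id_map`.
#' @param config A [pipeline_config()]. Its `region` is required.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return An object of class `mirgba_run` with elements `density`,
#'   `targets`, `topk`, `enrichment`, `consensus`, `map`, `network`,
#'   `overlap`, `top_genes`, `manifest`.
#' @export
run_pipeline <- function(paths, config = pipeline_config(),
                         out_dir = NULL) {
  if (is.null(config$region))
    stop_config("configuration must define the query region")
  need <- c("gff", "scores_tool1", "scores_tool2", "gmt", "edges",
            "candidates_gwas", "candidates_cnv", "relevance",
            "dysregulated")
  id_map <- if (!is.null(paths$id_map)) read_id_map(paths$id_map) else NULL
  stage_of <- c(gff = "annotation", scores_tool1 = "targets",
                scores_tool2 = "targets", gmt = "enrichment",
                edges = "network", candidates_gwas = "network",
                candidates_cnv = "network", relevance = "network",
                dysregulated = "overlap")
  for (key in need) {
    if (is.null(paths[[key]]) || !file.exists(paths[[key]]))
      stop(errorCondition(
        sprintf("stage '%s': missing input file '%s'",
                stage_of[[key]], key),
        class = c("mirgba_stage_error", "mirgba_error")))
  }

  loci <- .stage("annotation", read_mirna_gff(paths$gff))

  density <- .stage("density",
    region_density(loci, config$region,
                   flank_bp = config$window_flank_bp))

  integrated <- .stage("targets", {
    s1 <- read_score_table(paths$scores_tool1, "tool1",
                           polarity = "smaller_is_stronger",
                           id_map = id_map)
    s2 <- read_score_table(paths$scores_tool2, "tool2",
                           polarity = "larger_is_stronger",
                           id_map = id_map)
    integrate_scores(s1, s2, loci, k_levels = config$topk_levels)
  })
  region_ids <- loci$mirna_id[loci$chrom == config$region$chrom &
                                loci$start >= config$region$start &
                                loci$end <= config$region$end]
  region_ids <- intersect(region_ids, names(integrated$topk))

  enrich <- .stage("enrichment", {
    sets <- read_gmt(paths$gmt, id_map = id_map)
    background <- sort(unique(integrated$targets$gene))
    res <- enrich_targets(integrated$topk[region_ids], sets,
                          background = background,
                          min_size = config$geneset_min,
                          max_size = config$geneset_max)
    cons <- consensus_filter(res, nominal_p = config$nominal_p,
                             short_list_p = config$short_list_p,
                             min_runs = config$consensus_min_runs,
                             fdr_border = config$fdr_border)
    map <- enrichment_map_export(cons, attr(res, "filtered_sets"),
                                 similarity_threshold =
                                   config$similarity_threshold)
    list(results = res, consensus = cons, map = map)
  })

  network <- .stage("network", {
    edges <- read_edge_list(paths$edges,
                            weight_min = config$edge_weight_min,
                            id_map = id_map)
    gwas <- read_id_list(paths$candidates_gwas)
    cnv <- read_id_list(paths$candidates_cnv)
    ann <- read_relevance(paths$relevance)
    net <- construct_disease_network(
      edges, gwas, cnv, ann,
      candidate_criteria_min = config$candidate_criteria_min,
      partner_criteria_min = config$partner_criteria_min,
      weights = c(penalty = config$score_penalty,
                  brain = config$score_brain,
                  candidate = config$score_candidate),
      retain_min = config$retain_score_min)
    net$universe <- attr(edges, "nodes")
    net$edge_counts <- list(
      n_dropped_weight = attr(edges, "n_dropped_weight"),
      n_dropped_loops = attr(edges, "n_dropped_loops"),
      n_edges_kept = nrow(edges))
    net
  })

  overlap <- .stage("overlap", {
    dys <- read_id_list(paths$dysregulated)
    region_set <- region_target_union(integrated$topk[region_ids],
                                      k = config$overlap_k)
    dg <- dgcr8_set(integrated$topk, dys,
                    min_mirnas = config$min_dysregulated_mirnas,
                    exclude = region_set, k = config$overlap_k)
    tests <- list(
      region_mirna = overlap_test(region_set, network$nodes$gene,
                                  network$universe),
      dgcr8 = overlap_test(dg, network$nodes$gene, network$universe))
    ranking <- rank_by_score(network)
    top <- annotate_top_genes(ranking, region_set, dg,
                              top_n = config$top_n_genes)
    list(region_set = region_set, dgcr8_set = dg, tests = tests,
         top_genes = top)
  })

  manifest <- .build_manifest(config, loci, density, integrated, enrich,
                              network, overlap)
  run <- structure(list(density = density, targets = integrated$targets,
                        topk = integrated$topk,
                        enrichment = enrich$results,
                        consensus = enrich$consensus, map = enrich$map,
                        network = network, overlap = overlap$tests,
                        region_set = overlap$region_set,
                        dgcr8_set = overlap$dgcr8_set,
                        top_genes = overlap$top_genes,
                        manifest = manifest),
                   class = "mirgba_run")
  if (!is.null(out_dir)) .write_run(run, out_dir)
  run
}

.build_manifest <- function(config, loci, density, integrated, enrich,
                            network, overlap) {
  cfg <- unclass(config)
  cfg$region <- sprintf("%s:%d-%d", config$region$chrom,
                        config$region$start, config$region$end)
  list(config = cfg,
       counts = list(
         n_loci = nrow(loci),
         n_region_loci = density$region_count,
         density_percentile = density$percentile_exceeded,
         n_targets_per_mirna = stats::setNames(
           vapply(integrated$topk, function(tk) tk$n_targets, integer(1)),
           names(integrated$topk)),
         excluded_mirnas = attr(integrated$targets, "excluded_mirnas"),
         n_genesets_tested = length(attr(enrich$results,
                                         "filtered_sets")),
         n_background_genes = length(attr(enrich$results, "background")),
         n_consensus_sets = sum(enrich$consensus$consensus),
         n_edges_kept = network$edge_counts$n_edges_kept,
         n_edges_dropped_weight = network$edge_counts$n_dropped_weight,
         network = network$counts,
         overlap = lapply(overlap$tests, function(t)
           list(a = unname(t$cells[["a"]]), n_mechanism = t$n_mechanism,
                p = t$p, or_sample = t$or_sample)),
         n_top_hit = attr(overlap$top_genes, "n_hit"),
         fraction_top_hit = attr(overlap$top_genes, "fraction_hit")),
       seed = config$rng_seed)
}

.write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  d <- run$density
  write_tsv(data.frame(region_count = d$region_count,
                       percentile_exceeded = d$percentile_exceeded,
                       n_comparison = d$n_comparison),
            file.path(out_dir, "density_summary.tsv"))
  write_tsv(data.frame(mirna_id = names(d$window_counts),
                       window_count = unname(d$window_counts)),
            file.path(out_dir, "window_counts.tsv"))
  write_tsv(as.data.frame(run$targets),
            file.path(out_dir, "targets.tsv"))
  summ <- do.call(rbind, lapply(run$topk, function(tk)
    data.frame(mirna_id = tk$mirna_id, n_targets = tk$n_targets,
               mean_top_score = tk$mean_scores[[1]],
               stringsAsFactors = FALSE)))
  write_tsv(summ, file.path(out_dir, "targets_summary.tsv"))
  write_tsv(as.data.frame(run$enrichment),
            file.path(out_dir, "enrichment_results.tsv"))
  write_tsv(as.data.frame(run$consensus),
            file.path(out_dir, "enrichment_consensus.tsv"))
  write_tsv(run$map$nodes, file.path(out_dir, "map_nodes.tsv"))
  write_tsv(run$map$edges, file.path(out_dir, "map_edges.tsv"))
  write_tsv(run$network$nodes, file.path(out_dir, "network_nodes.tsv"))
  write_tsv(run$network$edges, file.path(out_dir, "network_edges.tsv"))
  ov <- do.call(rbind, lapply(run$overlap, function(t)
    data.frame(mechanism = t$mechanism, a = t$cells[["a"]],
               b = t$cells[["b"]], c = t$cells[["c"]], d = t$cells[["d"]],
               p = t$p, or_sample = t$or_sample, or_cmle = t$or_cmle,
               stringsAsFactors = FALSE)))
  write_tsv(ov, file.path(out_dir, "overlap_tests.tsv"))
  write_tsv(run$top_genes, file.path(out_dir, "top_genes.tsv"))
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.mirgba_run <- function(x, ...) {
  m <- x$manifest$counts
  cat("mirgba pipeline run\n")
  cat(sprintf("  loci: %d (%d in region; density percentile %.3f)\n",
              m$n_loci, m$n_region_loci, m$density_percentile))
  cat(sprintf("  gene-sets tested: %d over a %d-gene background; %d consensus hits\n",
              m$n_genesets_tested, m$n_background_genes,
              m$n_consensus_sets))
  cat(sprintf("  network: %d nodes / %d edges\n",
              m$network$n_nodes, m$network$n_edges))
  for (nm in names(x$overlap)) {
    t <- x$overlap[[nm]]
    cat(sprintf("  overlap %s: %d/%d in network, p = %.3g, OR = %.2f\n",
                nm, t$n_in_network, t$n_mechanism, t$p, t$or_sample))
  }
  cat(sprintf("  top-%d genes hit by either mechanism: %d (%.0f%%)\n",
              nrow(x$top_genes), m$n_top_hit, 100 * m$fraction_top_hit))
  invisible(x)
}
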