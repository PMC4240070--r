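# Seeded synthetic-data generator. Emulates every input the pipeline
# consumes — miRNA annotation with a planted cluster, two tool score
# tables with inter-tool agreement and planted gene-set enrichment, a
# gene-set collection, and a weighted interaction network with a dense
# candidate-linked core plus relevance annotations — so the whole chain
# is testable without external downloads.

#' Specification of a synthetic fixture bundle
#'
#' Defaults emulate the study conditions of a typical CNV-region miRNA
#' analysis at desk scale: a 7-miRNA cluster inside a 2.6 Mb window on a
#' background of genome-wide loci, ~2,000 genes, two prediction tools
#' with 70% target agreement, candidate lists of 35 and 107 genes sharing
#' one gene, and brain-relevance marginals close to the fractions seen in
#' brain expression/function/phenotype annotation resources.
#'
#' @param n_chromosomes,chrom_length_bp Genome shape.
#' @param n_background_mirnas Background loci placed uniformly at random.
#' @param cluster_size,cluster_span_bp Planted cluster: loci count and the
#'   window they must fit in.
#' @param n_genes Gene universe size (ids `G0001`...).
#' @param n_genesets,geneset_size_range Gene-set collection shape.
#' @param planted_enrichment `NULL` or a data.frame with columns
#'   `mirna_id`, `set_id`, `fraction`: that fraction of the miRNA's
#'   targets is drawn from the named set (must be at least the baseline
#'   hit rate implied by the set size).
#' @param targets_per_mirna Targets sampled per miRNA and tool.
#' @param intertool_overlap Fraction of each miRNA's targets shared
#'   between the two tools.
#' @param n_candidates_gwas,n_candidates_cnv,shared_candidates Candidate
#'   list sizes and their intersection.
#' @param relevance_marginals Probabilities of the three relevance flags.
#' @param candidate_relevance_factor Multiplier applied to the relevance
#'   marginals for candidate genes (probabilities capped at 1). Candidate
#'   lists are curated partly for brain relevance, so their flag rates run
#'   well above background; the default reproduces a retention of roughly
#'   five of six candidates at the 1-of-3 filter.
#' @param ppi_mean_degree Mean degree of the geometric degree model.
#' @param core_density_boost Extra candidate-directed edges added to each
#'   designated core-partner gene (0 = no planted core).
#' @param n_core_partners Number of designated core-partner genes.
#' @param weight_subthreshold_frac Fraction of edge weights drawn below
#'   0.02 (exercises the weight filter).
#' @param n_dysregulated Background miRNAs labeled as dysregulated by the
#'   microprocessor mechanism.
#' @param dual_arm_prob Probability a locus has both mature arms.
#' @param dual_target_frac For dual-arm loci, fraction of targets hit by
#'   both arms (exercises arm averaging).
#' @param seed RNG seed; everything generated from a spec is a pure
#'   function of the spec.
#' @return A validated list of class `synth_spec`.
#' @export
synth_spec <- function(n_chromosomes = 4L, chrom_length_bp = 5e7,
                       n_background_mirnas = 60L, cluster_size = 7L,
                       cluster_span_bp = 2.6e6, n_genes = 2000L,
                       n_genesets = 40L, geneset_size_range = c(15L, 120L),
                       planted_enrichment = NULL,
                       targets_per_mirna = 700L, intertool_overlap = 0.7,
                       n_candidates_gwas = 35L, n_candidates_cnv = 107L,
                       shared_candidates = 1L,
                       relevance_marginals = c(expression = 0.45,
                                               functional = 0.16,
                                               phenotype = 0.17),
                       candidate_relevance_factor = 1.6,
                       ppi_mean_degree = 6, core_density_boost = 8,
                       n_core_partners = 40L,
                       weight_subthreshold_frac = 0.2,
                       n_dysregulated = 12L, dual_arm_prob = 0.4,
                       dual_target_frac = 0.1, seed = 1L) {
  spec <- list(n_chromosomes = as.integer(n_chromosomes),
               chrom_length_bp = chrom_length_bp,
               n_background_mirnas = as.integer(n_background_mirnas),
               cluster_size = as.integer(cluster_size),
               cluster_span_bp = cluster_span_bp,
               n_genes = as.integer(n_genes),
               n_genesets = as.integer(n_genesets),
               geneset_size_range = as.integer(geneset_size_range),
               planted_enrichment = planted_enrichment,
               targets_per_mirna = as.integer(targets_per_mirna),
               intertool_overlap = intertool_overlap,
               n_candidates_gwas = as.integer(n_candidates_gwas),
               n_candidates_cnv = as.integer(n_candidates_cnv),
               shared_candidates = as.integer(shared_candidates),
               relevance_marginals = relevance_marginals,
               candidate_relevance_factor = candidate_relevance_factor,
               ppi_mean_degree = ppi_mean_degree,
               core_density_boost = core_density_boost,
               n_core_partners = as.integer(n_core_partners),
               weight_subthreshold_frac = weight_subthreshold_frac,
               n_dysregulated = as.integer(n_dysregulated),
               dual_arm_prob = dual_arm_prob,
               dual_target_frac = dual_target_frac,
               seed = as.integer(seed))
  if (spec$cluster_span_bp > spec$chrom_length_bp)
    stop_config("cluster_span_bp exceeds chromosome length")
  if (spec$shared_candidates > min(spec$n_candidates_gwas,
                                   spec$n_candidates_cnv))
    stop_config("shared_candidates exceeds a candidate list size")
  if (spec$targets_per_mirna > spec$n_genes)
    stop_config("targets_per_mirna exceeds the gene universe")
  if (spec$intertool_overlap < 0 || spec$intertool_overlap > 1)
    stop_config("intertool_overlap must lie in [0, 1]")
  if (!is.null(planted_enrichment) &&
      !all(c("mirna_id", "set_id", "fraction") %in%
           names(planted_enrichment)))
    stop_config("planted_enrichment needs columns mirna_id, set_id, fraction")
  class(spec) <- "synth_spec"
  spec
}

.gene_universe <- function(spec) sprintf("G%04d", seq_len(spec$n_genes))

#' Generate a miRNA annotation with a planted cluster
#'
#' Background loci are placed uniformly at random per chromosome; one
#' cluster of `cluster_size` loci is planted inside a single
#' `cluster_span_bp` window on chromosome 1. The planted window is
#' attached as attribute `planted_region`.
#'
#' @param spec A [synth_spec()].
#' @return A [mirna_loci()] table (cluster loci first, ids `miR-R1`...;
#'   background ids `miR-B01`...), with attribute `planted_region`.
#' @export
gen_mirna_annotation <- function(spec) {
  with_seed(spec$seed + 101L, {
    span <- spec$cluster_span_bp
    len_max <- 150L
    if (span < len_max + 1 || span > spec$chrom_length_bp)
      stop_config("cluster span does not fit the chromosome")
    cs <- floor(stats::runif(1, 1, spec$chrom_length_bp - span))
    k <- spec$cluster_size
    c_len <- sample(60:len_max, k, replace = TRUE)
    c_start <- sort(floor(stats::runif(k, cs, cs + span - c_len)))
    n <- spec$n_background_mirnas
    b_chrom <- sprintf("chr%d", sample.int(spec$n_chromosomes, n,
                                           replace = TRUE))
    b_len <- sample(60:len_max, n, replace = TRUE)
    b_start <- floor(stats::runif(n, 1, spec$chrom_length_bp - b_len))
    # keep background loci off the planted window so the region holds
    # exactly cluster_size loci
    repeat {
      clash <- b_chrom == "chr1" & b_start <= cs + span - 1 &
        b_start + b_len - 1 >= cs
      if (!any(clash)) break
      b_start[clash] <- floor(stats::runif(sum(clash), 1,
                                           spec$chrom_length_bp -
                                             b_len[clash]))
    }
    ids <- c(sprintf("miR-R%d", seq_len(k)),
             sprintf("miR-B%02d", seq_len(n)))
    arms_pool <- ifelse(stats::runif(k + n) < spec$dual_arm_prob,
                        "5p,3p",
                        ifelse(stats::runif(k + n) < 0.5, "5p", "3p"))
    loci <- mirna_loci(
      mirna_id = ids,
      chrom = c(rep("chr1", k), b_chrom),
      start = c(c_start, b_start),
      end = c(c_start + c_len - 1, b_start + b_len - 1),
      strand = sample(c("+", "-"), k + n, replace = TRUE),
      arms = arms_pool)
    attr(loci, "planted_region") <-
      genomic_interval("chr1", cs, cs + span - 1)
    loci
  })
}

#' Generate a synthetic gene-set collection
#'
#' Set sizes are drawn uniformly from `geneset_size_range` and members
#' sampled without replacement from the gene universe.
#'
#' @param spec A [synth_spec()].
#' @return A `gene_sets` collection (ids `GS001`...).
#' @export
gen_genesets <- function(spec) {
  with_seed(spec$seed + 404L, {
    universe <- .gene_universe(spec)
    sizes <- sample(spec$geneset_size_range[1]:spec$geneset_size_range[2],
                    spec$n_genesets, replace = TRUE)
    sets <- lapply(sizes, function(s) sample(universe, s))
    names(sets) <- sprintf("GS%03d", seq_len(spec$n_genesets))
    structure(sets,
              descriptions = stats::setNames(
                rep("synthetic gene-set", length(sets)), names(sets)),
              class = "gene_sets")
  })
}

#' Generate two tools' prediction score tables
#'
#' For each miRNA locus and tool, `targets_per_mirna` genes are sampled;
#' a fraction `intertool_overlap` of each miRNA's targets is shared
#' between tools, and shared targets get positively correlated strengths
#' (a common latent strength plus tool noise). For every
#' `planted_enrichment` row, that fraction of the miRNA's targets is
#' drawn from the named gene-set (placed among the shared targets so the
#' two-tool intersection keeps the signal). Tool 1 raw scores are
#' oriented smaller-is-stronger; tool 2 larger-is-stronger — the two
#' polarities exercise orientation handling downstream.
#'
#' @param spec A [synth_spec()].
#' @param loci A [mirna_loci()] table.
#' @param genesets A `gene_sets` collection (needed when enrichment is
#'   planted).
#' @return List of two [score_table()]s, `tool1` and `tool2`.
#' @export
gen_prediction_scores <- function(spec, loci, genesets = NULL) {
  planted <- spec$planted_enrichment
  if (!is.null(planted) && is.null(genesets))
    stop_config("planted enrichment requires the gene-set collection")
  with_seed(spec$seed + 202L, {
    universe <- .gene_universe(spec)
    nt <- spec$targets_per_mirna
    n_shared <- round(spec$intertool_overlap * nt)
    n_unique <- nt - n_shared
    if (nt + n_unique > spec$n_genes)
      stop_config("gene universe too small for the requested target counts")
    rows1 <- list(); rows2 <- list()
    for (i in seq_len(nrow(loci))) {
      id <- loci$mirna_id[i]
      arms <- strsplit(loci$arms[i], ",")[[1]]
      planted_genes <- character()
      if (!is.null(planted)) {
        for (j in which(planted$mirna_id == id)) {
          sid <- planted$set_id[j]
          if (is.null(genesets[[sid]]))
            stop_config("planted set '%s' not in the collection", sid)
          frac <- planted$fraction[j]
          baseline <- length(genesets[[sid]]) / spec$n_genes
          if (frac < baseline)
            stop_config("enrichment fraction %.3f below baseline %.3f",
                        frac, baseline)
          n_plant <- round(frac * nt)
          if (n_plant > n_shared)
            stop_config("planted fraction exceeds the shared target block")
          pool <- setdiff(intersect(genesets[[sid]], universe),
                          planted_genes)
          if (n_plant > length(pool))
            stop_config("gene-set '%s' too small to plant %d targets",
                        sid, n_plant)
          planted_genes <- c(planted_genes, sample(pool, n_plant))
        }
      }
      rest <- setdiff(universe, planted_genes)
      shared <- c(planted_genes,
                  sample(rest, n_shared - length(planted_genes)))
      rest <- setdiff(rest, shared)
      uniq1 <- if (n_unique) sample(rest, n_unique) else character()
      uniq2 <- if (n_unique) sample(setdiff(rest, uniq1), n_unique)
               else character()
      g1 <- c(shared, uniq1); g2 <- c(shared, uniq2)
      s_shared <- stats::runif(length(shared))
      s1 <- c(s_shared, stats::runif(length(uniq1)))
      s2 <- c(s_shared, stats::runif(length(uniq2)))
      raw1 <- -(s1 + stats::rnorm(length(s1), 0, 0.15))
      raw2 <- s2 + stats::rnorm(length(s2), 0, 0.15)
      a1 <- .assign_arms(id, g1, arms, spec$dual_target_frac)
      a2 <- .assign_arms(id, g2, arms, spec$dual_target_frac)
      rows1[[i]] <- data.frame(mature_id = a1$mature_id,
                               gene = a1$gene,
                               raw_score = raw1[a1$idx] +
                                 a1$extra * stats::rnorm(length(a1$idx), 0, 0.05),
                               stringsAsFactors = FALSE)
      rows2[[i]] <- data.frame(mature_id = a2$mature_id,
                               gene = a2$gene,
                               raw_score = raw2[a2$idx] +
                                 a2$extra * stats::rnorm(length(a2$idx), 0, 0.05),
                               stringsAsFactors = FALSE)
    }
    t1 <- do.call(rbind, rows1); t2 <- do.call(rbind, rows2)
    list(tool1 = score_table("tool1", t1$mature_id, t1$gene, t1$raw_score,
                             polarity = "smaller_is_stronger"),
         tool2 = score_table("tool2", t2$mature_id, t2$gene, t2$raw_score,
                             polarity = "larger_is_stronger"))
  })
}

# Assign each target gene to a mature arm; a fraction of targets of
# dual-arm loci get a record for both arms (second record slightly
# perturbed via the `extra` indicator).
.assign_arms <- function(id, genes, arms, dual_frac) {
  n <- length(genes)
  if (length(arms) == 1L) {
    return(list(mature_id = sprintf("%s-%s", id, rep(arms, n)),
                gene = genes, idx = seq_len(n), extra = rep(0, n)))
  }
  arm_pick <- sample(arms, n, replace = TRUE)
  dual <- stats::runif(n) < dual_frac
  idx <- c(seq_len(n), which(dual))
  arm_all <- c(arm_pick, vapply(which(dual), function(i)
    setdiff(arms, arm_pick[i])[1], character(1)))
  list(mature_id = sprintf("%s-%s", id, arm_all),
       gene = genes[idx], idx = idx,
       extra = c(rep(0, n), rep(1, sum(dual))))
}

#' Generate the synthetic interaction network and gene annotations
#'
#' Degrees follow a geometric model with mean `ppi_mean_degree` (random
#' stub matching; self-loops and duplicate pairs dropped). Candidate
#' lists of the configured sizes share exactly `shared_candidates` genes.
#' Each designated core-partner gene receives `core_density_boost` extra
#' edges to randomly chosen candidates. Every gene gets three independent
#' relevance flags at the configured marginals, forced true for core
#' partners. Edge weights are drawn so that `weight_subthreshold_frac`
#' of them fall below 0.02.
#'
#' @param spec A [synth_spec()].
#' @return List with `edges` (`interaction_edges`, unfiltered),
#'   `candidates_gwas`, `candidates_cnv`, `core_partners`, `relevance`
#'   (a [relevance_annotation()]).
#' @export
gen_ppi_and_annotations <- function(spec) {
  with_seed(spec$seed + 303L, {
    universe <- .gene_universe(spec)
    gwas <- sample(universe, spec$n_candidates_gwas)
    shared <- sample(gwas, spec$shared_candidates)
    cnv <- c(shared, sample(setdiff(universe, gwas),
                            spec$n_candidates_cnv - spec$shared_candidates))
    candidates <- union(gwas, cnv)
    core <- sample(setdiff(universe, candidates), spec$n_core_partners)

    deg <- stats::rgeom(spec$n_genes, 1 / (spec$ppi_mean_degree + 1))
    stubs <- rep(universe, deg)
    stubs <- sample(stubs)
    if (length(stubs) %% 2L) stubs <- stubs[-length(stubs)]
    half <- length(stubs) / 2
    ea <- stubs[seq_len(half)]; eb <- stubs[half + seq_len(half)]
    boost <- round(spec$core_density_boost)
    if (boost > 0) {
      for (g in core) {
        extra <- sample(candidates, min(boost, length(candidates)))
        ea <- c(ea, rep(g, length(extra))); eb <- c(eb, extra)
      }
    }
    n_e <- length(ea)
    sub <- stats::runif(n_e) < spec$weight_subthreshold_frac
    w <- ifelse(sub, stats::runif(n_e, 0.001, 0.0199),
                stats::runif(n_e, 0.02, 0.3))
    edges <- suppressMessages(clean_edges(
      data.frame(gene_a = ea, gene_b = eb, weight = w,
                 stringsAsFactors = FALSE), weight_min = 0))

    m <- spec$relevance_marginals
    flags <- cbind(stats::runif(spec$n_genes) < m[[1]],
                   stats::runif(spec$n_genes) < m[[2]],
                   stats::runif(spec$n_genes) < m[[3]])
    # curated candidates run well above background relevance rates
    mc <- pmin(1, unlist(m) * spec$candidate_relevance_factor)
    ci <- match(candidates, universe)
    flags[ci, ] <- cbind(stats::runif(length(ci)) < mc[[1]],
                         stats::runif(length(ci)) < mc[[2]],
                         stats::runif(length(ci)) < mc[[3]])
    flags[match(core, universe), ] <- TRUE
    relevance <- relevance_annotation(universe, flags[, 1], flags[, 2],
                                      flags[, 3])
    list(edges = edges, candidates_gwas = gwas, candidates_cnv = cnv,
         core_partners = core, relevance = relevance)
  })
}

#' Pick the dysregulated-miRNA list for a synthetic bundle
#'
#' Samples `n_dysregulated` background (non-cluster) loci; deterministic
#' under the spec seed.
#'
#' @param spec A [synth_spec()].
#' @param loci Output of [gen_mirna_annotation()].
#' @return Character vector of locus ids.
#' @export
gen_dysregulated <- function(spec, loci) {
  with_seed(spec$seed + 505L, {
    background <- grep("^miR-B", loci$mirna_id, value = TRUE)
    sample(background, min(spec$n_dysregulated, length(background)))
  })
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Generates every input the pipeline reads and writes them as plain-text
#' files: `mirnas.gff3`, `tool1_scores.tsv`, `tool2_scores.tsv`,
#' `genesets.gmt`, `edges.tsv`, `candidates_gwas.txt`,
#' `candidates_cnv.txt`, `relevance.tsv`, `dysregulated_mirnas.txt`, and
#' `manifest.json` (spec echo plus the planted region). Identical specs
#' produce byte-identical bundles.
#'
#' @param spec A [synth_spec()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly; the manifest is also returned as attribute
#'   `manifest`.
#' @export
write_synth_bundle <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  loci <- gen_mirna_annotation(spec)
  sets <- gen_genesets(spec)
  scores <- gen_prediction_scores(spec, loci, sets)
  ppi <- gen_ppi_and_annotations(spec)
  dys <- gen_dysregulated(spec, loci)
  region <- attr(loci, "planted_region")

  write_mirna_gff(loci, file.path(dir, "mirnas.gff3"))
  write_score_table(scores$tool1, file.path(dir, "tool1_scores.tsv"))
  write_score_table(scores$tool2, file.path(dir, "tool2_scores.tsv"))
  write_gmt(sets, file.path(dir, "genesets.gmt"))
  write_edge_list(ppi$edges, file.path(dir, "edges.tsv"))
  writeLines(ppi$candidates_gwas, file.path(dir, "candidates_gwas.txt"))
  writeLines(ppi$candidates_cnv, file.path(dir, "candidates_cnv.txt"))
  write_relevance(ppi$relevance, file.path(dir, "relevance.tsv"))
  writeLines(dys, file.path(dir, "dysregulated_mirnas.txt"))

  manifest <- list(
    spec = unclass(spec),
    region = sprintf("%s:%d-%d", region$chrom, region$start, region$end),
    core_partners = sort(ppi$core_partners),
    n_loci = nrow(loci), n_edges = nrow(ppi$edges))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(structure(dir, manifest = manifest))
}
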