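# Readers and writers for every external format the pipeline touches:
# GFF3 miRNA annotation, GMT gene-set collections, TSV edge lists, TSV
# prediction-score tables, plain-text id lists and two-column id maps.
# All coordinates are 1-based inclusive (GFF3 convention).

#' Construct a genomic interval
#'
#' @param chrom Chromosome name (non-empty string).
#' @param start 1-based inclusive start position (`>= 1`).
#' @param end 1-based inclusive end position (`>= start`).
#' @param strand `"+"`, `"-"` or `"*"` (unknown).
#' @return An object of class `genomic_interval`.
#' @examples
#' genomic_interval("chr22", 18876416, 21465674)
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom))
    stop_validate("chrom must be a non-empty string")
  start <- as.numeric(start); end <- as.numeric(end)
  if (!is.finite(start) || start < 1)
    stop_validate("interval start must be >= 1 (got %s)", format(start))
  if (!is.finite(end) || end < start)
    stop_validate("interval end (%s) must be >= start (%s)",
                  format(end), format(start))
  if (!strand %in% c("+", "-", "*"))
    stop_validate("strand must be one of '+', '-', '*'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:%s-%s(%s)\n", x$chrom, format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE), x$strand))
  invisible(x)
}

#' Parse a region string of the form "chr22:18,876,416-21,465,674"
#'
#' Commas in the coordinates are ignored.
#'
#' @param text Region string `chrom:start-end`.
#' @return A [genomic_interval()].
#' @export
parse_region <- function(text) {
  m <- regmatches(text, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", text))[[1]]
  if (length(m) != 4L)
    stop_parse("cannot parse region '%s'; expected chrom:start-end", text)
  genomic_interval(m[2], as.numeric(gsub(",", "", m[3])),
                   as.numeric(gsub(",", "", m[4])))
}

.valid_arms <- c("5p", "3p")

#' Construct a table of miRNA primary-transcript loci
#'
#' The locus table is the unit of the density and target analyses: one row
#' per miRNA gene (primary transcript), with the set of mature arms (-5p,
#' -3p) known for it.
#'
#' @param mirna_id Character vector of unique locus identifiers.
#' @param chrom,start,end,strand Parallel coordinate vectors (1-based
#'   inclusive).
#' @param arms Character vector; comma-separated subsets of `"5p","3p"`
#'   with at least one member per locus.
#' @return A `data.frame` of class `mirna_loci`.
#' @export
mirna_loci <- function(mirna_id, chrom, start, end, strand = "+", arms = "5p") {
  n <- length(mirna_id)
  df <- data.frame(mirna_id = as.character(mirna_id),
                   chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = rep_len(as.character(strand), n),
                   arms = rep_len(as.character(arms), n),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$mirna_id))
    stop_validate("duplicate miRNA id(s): %s",
                  paste(unique(df$mirna_id[duplicated(df$mirna_id)]),
                        collapse = ", "))
  if (any(df$start < 1) || any(df$end < df$start))
    stop_validate("locus coordinates must satisfy 1 <= start <= end")
  bad <- !vapply(strsplit(df$arms, ","), function(a)
    length(a) >= 1L && all(a %in% .valid_arms), logical(1))
  if (any(bad))
    stop_validate("invalid arms field for %s",
                  paste(df$mirna_id[bad], collapse = ", "))
  class(df) <- c("mirna_loci", "data.frame")
  df
}

#' Read miRNA primary-transcript loci from a GFF3 file
#'
#' Only features of type `miRNA_primary_transcript` are kept. The attribute
#' column must carry `ID=` and may carry `arms=` (comma-separated subset of
#' `5p,3p`; defaults to `5p` when absent). Coordinates are taken verbatim
#' (1-based inclusive) and record order is preserved.
#'
#' @param path Path to a GFF3 file.
#' @return A [mirna_loci()] table.
#' @export
read_mirna_gff <- function(path) {
  if (!file.exists(path)) stop_parse("file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  recs <- list()
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L)
      stop_parse("line %d: expected 9 tab-separated fields, got %d",
                 i, length(f))
    if (f[3] != "miRNA_primary_transcript") next
    start <- suppressWarnings(as.numeric(f[4]))
    end <- suppressWarnings(as.numeric(f[5]))
    if (is.na(start) || is.na(end))
      stop_parse("line %d: non-numeric coordinates", i)
    if (start < 1 || end < start)
      stop_parse("line %d: invalid interval [%s, %s]", i, f[4], f[5])
    attrs <- .parse_gff_attrs(f[9], i)
    if (is.null(attrs[["ID"]]))
      stop_parse("line %d: missing ID attribute", i)
    recs[[length(recs) + 1L]] <- data.frame(
      mirna_id = attrs[["ID"]], chrom = f[1], start = start, end = end,
      strand = if (f[7] %in% c("+", "-")) f[7] else "*",
      arms = attrs[["arms"]] %||% "5p", stringsAsFactors = FALSE)
  }
  if (!length(recs)) {
    out <- mirna_loci(character(), character(), numeric(), numeric(),
                      character(), character())
    return(out)
  }
  df <- do.call(rbind, recs)
  mirna_loci(df$mirna_id, df$chrom, df$start, df$end, df$strand, df$arms)
}

.parse_gff_attrs <- function(text, line) {
  parts <- strsplit(text, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  kv <- strsplit(parts, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L))
    stop_parse("line %d: malformed attribute field '%s'", line, text)
  stats::setNames(lapply(kv, function(p) trimws(p[2])),
                  vapply(kv, function(p) trimws(p[1]), character(1)))
}

#' Write miRNA loci to GFF3
#'
#' @param loci A [mirna_loci()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mirna_gff <- function(loci, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\t.\tmiRNA_primary_transcript\t%s\t%s\t.\t%s\t.\tID=%s;arms=%s",
                     loci$chrom, format(loci$start, scientific = FALSE, trim = TRUE),
                     format(loci$end, scientific = FALSE, trim = TRUE),
                     loci$strand, loci$mirna_id, loci$arms))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT dialect: `set_id`, description, then one gene
#' per field. Duplicate genes within a line are deduplicated; empty sets
#' and duplicate set ids are rejected.
#'
#' @param path Path to a GMT file.
#' @param id_map Optional two-column data.frame (`from`, `to`) applied to
#'   gene identifiers; unmapped genes are dropped and counted in the
#'   `n_unmapped` attribute.
#' @return A named list of class `gene_sets`: `set_id -> character vector`,
#'   with a `descriptions` attribute.
#' @export
read_gmt <- function(path, id_map = NULL) {
  if (!file.exists(path)) stop_parse("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character(); n_unmapped <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop_parse("line %d: GMT record needs >= 3 fields, got %d",
                 i, length(f))
    id <- f[1]
    if (id %in% names(sets))
      stop_validate("duplicate gene-set id '%s' (line %d)", id, i)
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!is.null(id_map)) {
      mapped <- apply_id_map(genes, id_map)
      n_unmapped <- n_unmapped + attr(mapped, "n_unmapped")
      genes <- as.character(mapped)
    }
    if (!length(genes))
      stop_validate("gene-set '%s' (line %d) is empty", id, i)
    sets[[id]] <- genes
    desc[[id]] <- f[2]
  }
  structure(sets, descriptions = desc, n_unmapped = n_unmapped,
            class = "gene_sets")
}

#' Write a gene-set collection to GMT
#'
#' @param sets A `gene_sets` list (or plain named list of gene vectors).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||%
    stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]] %||% "", sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a weighted undirected interaction edge list
#'
#' TSV with columns `gene_a`, `gene_b`, `weight`. Edges below `weight_min`
#' are dropped, self-loops are dropped with a warning, and duplicate
#' unordered pairs are collapsed keeping the maximum weight, so downstream
#' modules can assume a simple graph.
#'
#' @param path Path to the TSV file.
#' @param weight_min Minimum retained weight (inclusive; default 0.02, the
#'   conventional false-positive filter for aggregated interaction weights).
#' @param id_map Optional two-column id map; edges with an unmapped
#'   endpoint are dropped and counted.
#' @return A `data.frame` of class `interaction_edges` with columns
#'   `gene_a`, `gene_b`, `weight`, plus attributes `nodes` (character) and
#'   `n_dropped_*` counters.
#' @export
read_edge_list <- function(path, weight_min = 0.02, id_map = NULL) {
  if (!file.exists(path)) stop_parse("file not found: %s", path)
  df <- read_tsv(path, colClasses = c("character", "character", "character"))
  if (!all(c("gene_a", "gene_b", "weight") %in% names(df)))
    stop_parse("edge list must have columns gene_a, gene_b, weight")
  w <- suppressWarnings(as.numeric(df$weight))
  if (anyNA(w))
    stop_parse("non-numeric weight at data row(s) %s",
               paste(utils::head(which(is.na(w)), 5), collapse = ", "))
  df$weight <- w
  n_unmapped <- 0L
  if (!is.null(id_map)) {
    a <- apply_id_map(df$gene_a, id_map, keep_na = TRUE)
    b <- apply_id_map(df$gene_b, id_map, keep_na = TRUE)
    drop <- is.na(a) | is.na(b)
    n_unmapped <- sum(drop)
    df <- df[!drop, , drop = FALSE]
    df$gene_a <- a[!drop]; df$gene_b <- b[!drop]
  }
  clean_edges(df, weight_min = weight_min, n_unmapped = n_unmapped)
}

# Shared edge-hygiene routine (also used on in-memory edge tables).
clean_edges <- function(df, weight_min = 0, n_unmapped = 0L) {
  loops <- df$gene_a == df$gene_b
  if (any(loops))
    mirgba_log("warn", "dropping %d self-loop edge(s)", sum(loops))
  df <- df[!loops, , drop = FALSE]
  n_below <- sum(df$weight < weight_min)
  df <- df[df$weight >= weight_min, , drop = FALSE]
  # canonicalise unordered pairs, keep max weight among duplicates
  a <- pmin(df$gene_a, df$gene_b); b <- pmax(df$gene_a, df$gene_b)
  key <- paste(a, b, sep = "\r")
  o <- order(key, -df$weight)
  keep <- !duplicated(key[o])
  out <- data.frame(gene_a = a[o][keep], gene_b = b[o][keep],
                    weight = df$weight[o][keep], stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            nodes = sort(unique(c(out$gene_a, out$gene_b))),
            n_dropped_loops = sum(loops),
            n_dropped_weight = n_below,
            n_dropped_unmapped = n_unmapped,
            weight_min = weight_min,
            class = c("interaction_edges", "data.frame"))
}

#' Write an interaction edge list to TSV
#'
#' @param edges An `interaction_edges` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  write_tsv(edges[, c("gene_a", "gene_b", "weight")], path)
}

#' Read a target-prediction score table for one tool
#'
#' TSV with columns `mature_id`, `gene`, `raw_score`. The score polarity
#' (whether larger or smaller raw scores mean stronger predictions) is
#' stored with the table so the percentile transformation can orient
#' scores correctly.
#'
#' @param path Path to the TSV file.
#' @param tool Tool label stored with each record.
#' @param polarity `"larger_is_stronger"` or `"smaller_is_stronger"`.
#' @param id_map Optional two-column gene id map; unmapped genes dropped
#'   and counted.
#' @return A `data.frame` of class `score_table` with columns `tool`,
#'   `mature_id`, `gene`, `raw_score` and a `polarity` attribute.
#' @export
read_score_table <- function(path, tool,
                             polarity = c("larger_is_stronger",
                                          "smaller_is_stronger"),
                             id_map = NULL) {
  polarity <- match.arg(polarity)
  if (!file.exists(path)) stop_parse("file not found: %s", path)
  df <- read_tsv(path)
  if (!all(c("mature_id", "gene", "raw_score") %in% names(df)))
    stop_parse("score table must have columns mature_id, gene, raw_score")
  s <- suppressWarnings(as.numeric(df$raw_score))
  if (anyNA(s))
    stop_parse("missing or non-numeric raw_score at data row(s) %s",
               paste(utils::head(which(is.na(s)), 5), collapse = ", "))
  df$raw_score <- s
  n_unmapped <- 0L
  if (!is.null(id_map)) {
    g <- apply_id_map(df$gene, id_map, keep_na = TRUE)
    n_unmapped <- sum(is.na(g))
    df <- df[!is.na(g), , drop = FALSE]
    df$gene <- g[!is.na(g)]
  }
  score_table(tool, df$mature_id, df$gene, df$raw_score, polarity,
              n_unmapped = n_unmapped)
}

#' Construct a score table in memory
#'
#' @inheritParams read_score_table
#' @param mature_id,gene,raw_score Parallel record vectors. `mature_id`
#'   carries the arm suffix (`-5p`/`-3p`).
#' @param n_unmapped Internal counter carried through from id mapping.
#' @return A `score_table` data.frame.
#' @export
score_table <- function(tool, mature_id, gene, raw_score,
                        polarity = c("larger_is_stronger",
                                     "smaller_is_stronger"),
                        n_unmapped = 0L) {
  polarity <- match.arg(polarity)
  df <- data.frame(tool = as.character(tool),
                   mature_id = as.character(mature_id),
                   gene = as.character(gene),
                   raw_score = as.numeric(raw_score),
                   stringsAsFactors = FALSE)
  key <- paste(df$mature_id, df$gene, sep = "\r")
  if (anyDuplicated(key))
    stop_validate("duplicate (mature_id, gene) record(s), e.g. %s",
                  sub("\r", " / ", key[duplicated(key)][1]))
  structure(df, polarity = polarity, n_unmapped = n_unmapped,
            class = c("score_table", "data.frame"))
}

#' Write a score table to TSV
#'
#' @param scores A `score_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  write_tsv(scores[, c("mature_id", "gene", "raw_score")], path)
}

#' Read a plain-text id list (one identifier per line)
#'
#' Blank lines and `#` comments are skipped.
#'
#' @param path Path to the list file.
#' @return Character vector of unique ids in file order.
#' @export
read_id_list <- function(path) {
  if (!file.exists(path)) stop_parse("file not found: %s", path)
  x <- trimws(readLines(path))
  unique(x[nzchar(x) & !grepl("^#", x)])
}

#' Read a two-column identifier mapping (TSV: from, to)
#'
#' @param path Path to the mapping file.
#' @return A data.frame with columns `from`, `to`.
#' @export
read_id_map <- function(path) {
  if (!file.exists(path)) stop_parse("file not found: %s", path)
  df <- read_tsv(path, colClasses = "character")
  if (ncol(df) < 2L) stop_parse("id map needs two columns")
  names(df)[1:2] <- c("from", "to")
  df[, 1:2]
}

# Map ids; unmapped entries -> NA (keep_na) or dropped; counts attached.
apply_id_map <- function(ids, id_map, keep_na = FALSE) {
  to <- id_map$to[match(ids, id_map$from)]
  n_unmapped <- sum(is.na(to))
  if (n_unmapped)
    mirgba_log("info", "%d identifier(s) not mapped", n_unmapped)
  out <- if (keep_na) to else to[!is.na(to)]
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Read a per-gene relevance annotation table
#'
#' TSV with columns `gene`, `expression_flag`, `function_flag`,
#' `phenotype_flag` (0/1 or TRUE/FALSE). These are the three
#' brain-relevance criteria (expression atlas, neuronal function gene-sets,
#' mouse neuro phenotype).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with logical flag columns and `criteria_met`.
#' @export
read_relevance <- function(path) {
  if (!file.exists(path)) stop_parse("file not found: %s", path)
  df <- read_tsv(path)
  need <- c("gene", "expression_flag", "function_flag", "phenotype_flag")
  if (!all(need %in% names(df)))
    stop_parse("relevance table must have columns %s",
               paste(need, collapse = ", "))
  for (col in need[-1]) df[[col]] <- as.logical(as.integer(df[[col]]))
  relevance_annotation(df$gene, df$expression_flag, df$function_flag,
                       df$phenotype_flag)
}

#' Construct a relevance-annotation table
#'
#' @param gene Gene ids (unique).
#' @param expression_flag,function_flag,phenotype_flag Logical vectors for
#'   the three brain-relevance criteria.
#' @return A data.frame of class `relevance_annotation` with
#'   `criteria_met` = number of criteria satisfied per gene.
#' @export
relevance_annotation <- function(gene, expression_flag, function_flag,
                                 phenotype_flag) {
  if (anyDuplicated(gene))
    stop_validate("duplicate gene(s) in relevance annotation")
  df <- data.frame(gene = as.character(gene),
                   expression_flag = as.logical(expression_flag),
                   function_flag = as.logical(function_flag),
                   phenotype_flag = as.logical(phenotype_flag),
                   stringsAsFactors = FALSE)
  df$criteria_met <- rowSums(df[, 2:4])
  class(df) <- c("relevance_annotation", "data.frame")
  df
}

#' Write a relevance-annotation table to TSV
#'
#' @param ann A `relevance_annotation` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_relevance <- function(ann, path) {
  out <- ann[, c("gene", "expression_flag", "function_flag",
                 "phenotype_flag")]
  for (col in names(out)[-1]) out[[col]] <- as.integer(out[[col]])
  write_tsv(out, path)
}
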