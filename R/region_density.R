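# miRNA density of a query region relative to same-sized windows centred
# on every other miRNA locus genome-wide.

#' Count miRNA loci fully contained in a region
#'
#' A locus counts only if its whole primary-transcript interval lies inside
#' the region (same chromosome, `start >= region$start`,
#' `end <= region$end`). Loci straddling a boundary are not counted.
#'
#' @param loci A [mirna_loci()] table.
#' @param region A [genomic_interval()].
#' @param start_only If `TRUE`, count loci whose transcript start (not the
#'   whole interval) falls inside the region.
#' @return Integer count.
#' @export
count_in_region <- function(loci, region, start_only = FALSE) {
  if (!nrow(loci)) return(0L)
  same <- loci$chrom == region$chrom
  if (start_only) {
    sum(same & loci$start >= region$start & loci$start <= region$end)
  } else {
    sum(same & loci$start >= region$start & loci$end <= region$end)
  }
}

#' Windowed miRNA counts around every locus
#'
#' For each locus the window is the symmetric interval
#' `[start - flank_bp, start + flank_bp]` on its own chromosome (clipped at
#' position 1; windows never span chromosomes), and the count is the number
#' of loci fully contained in that window. The centring locus is always
#' contained in its own window, so every count is at least 1.
#'
#' @param loci A [mirna_loci()] table.
#' @param flank_bp Flank size in bp on either side of the transcript start
#'   (default 1,300,000, i.e. a symmetric 2.6 Mb window).
#' @param start_only If `TRUE`, containment is judged on transcript starts
#'   rather than whole intervals.
#' @return Named integer vector, `mirna_id -> count`.
#' @export
window_counts <- function(loci, flank_bp = 1.3e6, start_only = FALSE) {
  if (flank_bp <= 0) stop_validate("flank_bp must be positive")
  n <- nrow(loci)
  counts <- integer(n)
  if (n) {
    for (ch in unique(loci$chrom)) {
      idx <- which(loci$chrom == ch)
      s <- loci$start[idx]; e <- loci$end[idx]
      ws <- pmax(1, s - flank_bp); we <- s + flank_bp
      # sorted sweep: count loci with start >= ws and end <= we
      if (start_only) {
        os <- sort(s)
        counts[idx] <- vapply(seq_along(idx), function(i) {
          sum(os >= ws[i] & os <= we[i])
        }, numeric(1))
      } else {
        counts[idx] <- vapply(seq_along(idx), function(i) {
          sum(s >= ws[i] & e <= we[i])
        }, numeric(1))
      }
    }
  }
  stats::setNames(as.integer(counts), loci$mirna_id)
}

#' Density percentile of a region count against locus-centred windows
#'
#' Fraction of comparison windows whose miRNA count is strictly below the
#' query region's count. Windows centred on loci inside the query region
#' are conventionally excluded ("other" loci), via `exclude_ids`.
#'
#' @param region_count Integer count of loci in the query region.
#' @param window_counts Named integer vector from [window_counts()].
#' @param exclude_ids Locus ids to drop from the comparison set.
#' @return Fraction in `[0, 1]`.
#' @export
density_percentile <- function(region_count, window_counts,
                               exclude_ids = character()) {
  keep <- setdiff(names(window_counts), exclude_ids)
  if (!length(keep))
    stop_compute("no comparison windows left after exclusion")
  mean(window_counts[keep] < region_count)
}

#' Region miRNA-density summary
#'
#' Runs [count_in_region()], [window_counts()] and [density_percentile()]
#' in one call.
#'
#' @inheritParams window_counts
#' @param region Query [genomic_interval()].
#' @param exclude_region_loci Exclude windows centred on loci inside the
#'   query region from the percentile comparison (default `TRUE`).
#' @return An object of class `density_result` with fields `region_count`,
#'   `window_counts`, `percentile_exceeded`, `n_comparison`.
#' @export
region_density <- function(loci, region, flank_bp = 1.3e6,
                           start_only = FALSE, exclude_region_loci = TRUE) {
  rc <- count_in_region(loci, region, start_only = start_only)
  wc <- window_counts(loci, flank_bp = flank_bp, start_only = start_only)
  excl <- character()
  if (exclude_region_loci && nrow(loci)) {
    inside <- loci$chrom == region$chrom &
      loci$start >= region$start & loci$end <= region$end
    excl <- loci$mirna_id[inside]
  }
  pct <- density_percentile(rc, wc, exclude_ids = excl)
  structure(list(region_count = rc, window_counts = wc,
                 percentile_exceeded = pct,
                 n_comparison = length(setdiff(names(wc), excl)),
                 flank_bp = flank_bp, region = region),
            class = "density_result")
}

#' @export
print.density_result <- function(x, ...) {
  cat("miRNA density summary\n")
  cat(sprintf("  region: %s:%s-%s\n", x$region$chrom,
              format(x$region$start, scientific = FALSE),
              format(x$region$end, scientific = FALSE)))
  cat(sprintf("  loci in region: %d\n", x$region_count))
  cat(sprintf("  comparison windows (+/- %s bp): %d\n",
              format(x$flank_bp, big.mark = ",", scientific = FALSE),
              x$n_comparison))
  cat(sprintf("  windows with fewer loci than the region: %.1f%%\n",
              100 * x$percentile_exceeded))
  invisible(x)
}
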