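# Internal helpers: logging, seeded evaluation, small validators.

.log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Set the package log level
#'
#' Messages are written to stderr. Levels, from most to least verbose:
#' `"debug"`, `"info"`, `"warn"`, `"error"`.
#'
#' @param level One of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return The previous level, invisibly.
#' @export
mirgba_log_level <- function(level = c("info", "debug", "warn", "error")) {
  level <- match.arg(level)
  old <- getOption("mirgba.log_level", "info")
  options(mirgba.log_level = level)
  invisible(old)
}

mirgba_log <- function(level, fmt, ...) {
  threshold <- .log_levels[[getOption("mirgba.log_level", "info")]]
  if (.log_levels[[level]] >= threshold) {
    message(sprintf("[%s] %s", toupper(level), sprintf(fmt, ...)))
  }
  invisible(NULL)
}

# Evaluate `expr` under a fixed seed without clobbering the caller's RNG
# stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_parse <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("mirgba_parse_error", "mirgba_error")))
}

stop_validate <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("mirgba_validation_error", "mirgba_error")))
}

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("mirgba_config_error", "mirgba_error")))
}

stop_compute <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("mirgba_computation_error", "mirgba_error")))
}

# TSV writers/readers used across modules; all outputs carry a header row.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
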