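#' @keywords internal
"_PACKAGE"

## Structured logging: one record per event, collected in an environment so
## tests can inspect what a run reported without parsing console output.

.log_env <- new.env(parent = emptyenv())
.log_env$records <- list()

#' Append a structured log record
#'
#' @param stage character, pipeline stage emitting the record.
#' @param level one of "info", "warn", "error".
#' @param message human-readable message.
#' @param ... named parameters stored with the record.
#' @keywords internal
cm_log <- function(stage, level, message, ...) {
  rec <- list(stage = stage, level = level, message = message,
              params = list(...), time = Sys.time())
  .log_env$records[[length(.log_env$records) + 1L]] <- rec
  if (identical(getOption("cardiomet.verbose", FALSE), TRUE)) {
    message(sprintf("[%s] %s: %s", stage, level, message))
  }
  invisible(rec)
}

#' Retrieve or clear the structured log
#'
#' @param clear logical; if TRUE the log is emptied after retrieval.
#' @return list of log records.
#' @export
cm_get_log <- function(clear = FALSE) {
  out <- .log_env$records
  if (clear) .log_env$records <- list()
  out
}

#' Derive a stage-specific seed from a global seed
#'
#' A single run seed is fanned out to the stages by a fixed affine map so
#' stages are reproducible yet use independent streams. Result stays below
#' 2^31 so it is a valid R integer seed.
#'
#' @param seed global integer seed.
#' @param stage stage name (character).
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483647)
}

## small input checkers used throughout
.check_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  if (x > upper)
    stop(sprintf("'%s' must be <= %g", name, upper), call. = FALSE)
  invisible(TRUE)
}
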