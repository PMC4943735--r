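#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards. All seeded entry points route through
# this so a fixed seed gives bitwise-identical results regardless of what
# the session RNG was doing before.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic derived seed for sub-streams, kept inside 32-bit range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483587)
}

stop_validation <- function(...) {
  stop(..., call. = FALSE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Write a JSON run log
#'
#' Batch drivers record the resolved parameters of a run (configuration,
#' seed, per-image calibration gains, ...) as a small JSON file so a run can
#' be audited and reproduced.
#'
#' @param log A named list of parameters and results to record.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(log, path) {
  stopifnot(is.list(log), is.character(path), length(path) == 1L)
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
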