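# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base `round()` rounds half to even; the correlation-class bands need
#' commercial rounding so that e.g. 44.5 maps to 45.
#' @param x numeric vector
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != trunc(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

# Derive a bounded per-stage seed from a global seed (documented fan-out:
# stage seeds are `seed + offset`, kept below .Machine$integer.max).
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483647)
}
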