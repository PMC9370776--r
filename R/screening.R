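# Avenue I: per-taxon correlation screening against the two responses and
# the banded correlation class used as evidence weight in the final score.

#' Correlate every taxon with a response
#'
#' @param X a [predictor_matrix()] (or plain matrix) of proportions
#' @param y numeric response (relative weight loss or BMI change)
#' @param method correlation coefficient; Pearson by default because the
#'   downstream models are linear, Spearman available for sensitivity checks
#' @return data.frame with columns `taxon_id`, `r`, `abs_r`, `rank`
#'   (1 = strongest |r|, average ranks for ties), sorted by decreasing |r|
#' @export
correlate_all <- function(X, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as_design(X)
  if (nrow(x) != length(y)) {
    stop("length of y does not match the number of samples", call. = FALSE)
  }
  if (stats::sd(y) == 0) stop("y is constant", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  r <- rep(0, ncol(x))
  ok <- sds > 0
  if (any(!ok)) {
    warning(sum(!ok), " constant taxon column(s) assigned r = 0",
            call. = FALSE)
  }
  if (any(ok)) {
    r[ok] <- suppressWarnings(
      as.numeric(stats::cor(x[, ok, drop = FALSE], y, method = method)))
  }
  out <- data.frame(taxon_id = colnames(x), r = r, abs_r = abs(r),
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$abs_r, ties.method = "average")
  out[order(-out$abs_r, out$taxon_id), , drop = FALSE]
}

#' Banded correlation class
#'
#' Grades how strongly a taxon correlates with *both* responses. The
#' strength is the smaller of the two absolute correlations, expressed in
#' percent and rounded to the nearest full percent (half away from zero);
#' it maps through half-open bands `[45,50) -> 0.5`, `[50,55) -> 1`,
#' `[55,60) -> 1.5`, `[60,100] -> 2`, below 45 -> 0. The class carries the
#' common sign of the two correlations; if their signs differ the class
#' is 0.
#'
#' @param r_rwl,r_dbmi correlations with the two responses, in `[-1, 1]`
#' @param band_edges increasing percent thresholds of the four bands
#' @return signed class values in `{0, ±0.5, ±1, ±1.5, ±2}` (vectorized)
#' @export
correlation_class <- function(r_rwl, r_dbmi, band_edges = c(45, 50, 55, 60)) {
  if (any(abs(c(r_rwl, r_dbmi)) > 1 + 1e-12, na.rm = TRUE)) {
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  }
  stopifnot(length(band_edges) == 4L, !is.unsorted(band_edges))
  n <- max(length(r_rwl), length(r_dbmi))
  r_rwl <- rep_len(r_rwl, n)
  r_dbmi <- rep_len(r_dbmi, n)
  strength <- round_half_up(pmin(abs(r_rwl), abs(r_dbmi)) * 100)
  mag <- findInterval(strength, band_edges) / 2
  sgn <- ifelse(sign(r_rwl) == sign(r_dbmi), sign(r_rwl), 0)
  ifelse(sgn == 0, 0, sgn * mag)
}

#' Screen all taxa against both responses
#'
#' Convenience wrapper producing one correlation record per taxon: the two
#' correlations and the banded class.
#'
#' @inheritParams correlate_all
#' @param rwl relative weight loss response (percent)
#' @param dbmi BMI-change response (kg/m2)
#' @param band_edges passed to [correlation_class()]
#' @return data.frame `taxon_id`, `r_rwl`, `r_dbmi`, `corr_class`, sorted by
#'   decreasing `min(|r_rwl|, |r_dbmi|)`
#' @export
screen_taxa <- function(X, rwl, dbmi, method = c("pearson", "spearman"),
                        band_edges = c(45, 50, 55, 60)) {
  method <- match.arg(method)
  c1 <- correlate_all(X, rwl, method)
  c2 <- correlate_all(X, dbmi, method)
  c2 <- c2[match(c1$taxon_id, c2$taxon_id), ]
  out <- data.frame(taxon_id = c1$taxon_id, r_rwl = c1$r, r_dbmi = c2$r,
                    stringsAsFactors = FALSE)
  out$corr_class <- correlation_class(out$r_rwl, out$r_dbmi, band_edges)
  out[order(-pmin(abs(out$r_rwl), abs(out$r_dbmi)), out$taxon_id), ,
      drop = FALSE]
}
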