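# Sparse k-term prediction models: exhaustive best-subset search over the
# final candidate set, cross-validated R-squared from averaged out-of-fold
# predictions, and per-patient classification against the 10% weight-loss
# threshold.

#' Best k-term linear models by exhaustive search
#'
#' Evaluates every size-k subset of the candidate terms by OLS and keeps the
#' one with the lowest AICc per k (ties broken by smaller RSS, then by
#' lexicographic term order, which the column-major enumeration yields
#' automatically). Singular subsets are skipped with a warning.
#'
#' @param X a [predictor_matrix()] or matrix
#' @param y response vector
#' @param terms candidate term names (the fused final list)
#' @param k_range model sizes to search (default 1 to 5)
#' @return named list of [fit_ols()] results, one per k (`"k1"`, `"k2"`, ...)
#' @export
best_k_term_models <- function(X, y, terms = NULL, k_range = 1:5) {
  x <- as_design(X)
  terms <- sort(terms %||% colnames(x))
  if (!all(terms %in% colnames(x))) stop("unknown terms", call. = FALSE)
  n <- length(y)
  if (max(k_range) > length(terms)) {
    stop("k_range exceeds the number of candidate terms", call. = FALSE)
  }
  if (n <= max(k_range) + 2) {
    stop("not enough samples for the largest model size", call. = FALSE)
  }
  out <- vector("list", length(k_range))
  names(out) <- paste0("k", k_range)
  n_singular <- 0L
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    combos <- utils::combn(terms, k)
    best <- NULL
    best_aicc <- Inf
    best_rss <- Inf
    for (j in seq_len(ncol(combos))) {
      sub <- combos[, j]
      f <- stats::lm.fit(cbind(1, x[, sub, drop = FALSE]), y)
      if (any(is.na(f$coefficients))) { n_singular <- n_singular + 1L; next }
      rss <- sum(f$residuals^2)
      aicc <- aicc_from_rss(max(rss, 1e-12), n, k)
      if (aicc < best_aicc - 1e-12 ||
          (abs(aicc - best_aicc) <= 1e-12 && rss < best_rss - 1e-12)) {
        best <- sub
        best_aicc <- aicc
        best_rss <- rss
      }
    }
    if (is.null(best)) stop("all size-", k, " subsets were singular",
                            call. = FALSE)
    out[[ki]] <- fit_ols(x[, best, drop = FALSE], y)
  }
  if (n_singular > 0L) {
    warning(n_singular, " singular subset(s) skipped", call. = FALSE)
  }
  out
}

#' Cross-validated R-squared from averaged out-of-fold predictions
#'
#' Repeatedly draws random fold assignments (optionally stratified, e.g. by
#' PS/NS group so no fold is empty of one outcome class), refits the model
#' on each training split, and averages each sample's out-of-fold
#' predictions over the repeats. `R2 = 1 - sum((y - yhat_avg)^2) /
#' sum((y - mean(y))^2)`. With as many folds as samples this is
#' leave-one-out: deterministic, computed in a single pass.
#'
#' @param X a [predictor_matrix()] or matrix
#' @param y response vector
#' @param terms model terms
#' @param n_folds number of folds (e.g. 3, 5, 8, or 15 at n = 15)
#' @param n_repeats repeated fold assignments (ignored for leave-one-out)
#' @param seed RNG seed for the fold draws
#' @param strata optional factor for stratified fold assignment
#' @return the cross-validated R-squared (a single number, can be negative)
#' @export
cv_r2 <- function(X, y, terms, n_folds, n_repeats = 200L, seed = 1L,
                  strata = NULL) {
  x <- as_design(X)[, terms, drop = FALSE]
  n <- length(y)
  if (n_folds > n) stop("more folds than samples", call. = FALSE)
  loo <- n_folds == n

  predict_folds <- function(fid) {
    pred <- numeric(n)
    for (f in unique(fid)) {
      test <- fid == f
      fit <- stats::lm.fit(cbind(1, x[!test, , drop = FALSE]), y[!test])
      if (any(is.na(fit$coefficients))) {
        stop("singular training design in a CV fold", call. = FALSE)
      }
      pred[test] <- cbind(1, x[test, , drop = FALSE]) %*% fit$coefficients
    }
    pred
  }

  if (loo) {
    yhat <- predict_folds(seq_len(n))
  } else {
    set.seed(seed)
    acc <- numeric(n)
    for (r in seq_len(n_repeats)) {
      if (is.null(strata)) {
        fid <- sample(rep_len(seq_len(n_folds), n))
      } else {
        fid <- integer(n)
        for (s in unique(strata)) {
          idx <- which(strata == s)
          fid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
        }
      }
      acc <- acc + predict_folds(fid)
    }
    yhat <- acc / n_repeats
  }
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

#' Tally per-patient classification labels
#'
#' @param labels character vector with values `"correct(+)"`,
#'   `"correct(-)"`, `"overpredicted"`, `"underpredicted"`
#' @return list with `counts` (named integer vector over the four labels),
#'   `sum_correct` and `sum_incorrect`
#' @export
tally_classifications <- function(labels) {
  lv <- c("correct(+)", "correct(-)", "overpredicted", "underpredicted")
  bad <- setdiff(unique(labels), lv)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  counts <- table(factor(labels, levels = lv))
  counts <- stats::setNames(as.integer(counts), lv)
  list(counts = counts,
       sum_correct = counts[["correct(+)"]] + counts[["correct(-)"]],
       sum_incorrect = counts[["overpredicted"]] + counts[["underpredicted"]])
}

#' Classify predicted vs actual weight loss
#'
#' A patient is `correct(+)` when significant weight loss (at or above the
#' threshold) occurred and was predicted, `correct(-)` when it neither
#' occurred nor was predicted, `overpredicted` when predicted but absent,
#' and `underpredicted` when present but not predicted. The boundary is
#' inclusive: a value exactly at the threshold counts as significant.
#'
#' @param predicted predicted response values
#' @param actual observed response values
#' @param threshold significance threshold (default 10, i.e. 10% relative
#'   weight loss)
#' @return object of class `classification_table`: list with a per-patient
#'   data.frame `table` and the [tally_classifications()] `tallies`
#' @export
classify_predictions <- function(predicted, actual, threshold = 10) {
  if (length(predicted) != length(actual)) {
    stop("predicted and actual must have equal length", call. = FALSE)
  }
  pa <- actual >= threshold
  pp <- predicted >= threshold
  labels <- ifelse(pa & pp, "correct(+)",
                   ifelse(!pa & !pp, "correct(-)",
                          ifelse(pp, "overpredicted", "underpredicted")))
  tab <- data.frame(patient = seq_along(actual), predicted = predicted,
                    actual = actual, label = labels, stringsAsFactors = FALSE)
  structure(list(table = tab, tallies = tally_classifications(labels),
                 threshold = threshold),
            class = "classification_table")
}

#' @export
print.classification_table <- function(x, ...) {
  t <- x$tallies
  cat(sprintf("<classification_table> threshold %.1f: %s; sum correct %d / incorrect %d\n",
              x$threshold,
              paste(names(t$counts), t$counts, sep = "=", collapse = ", "),
              t$sum_correct, t$sum_incorrect))
  invisible(x)
}

#' Relative standard errors of coefficients
#'
#' `100 * |se / estimate|` per coefficient; undefined (missing) for zero
#' estimates.
#'
#' @param coefficients coefficient estimates
#' @param se their standard errors
#' @return percent relative standard errors, `NA` where the estimate is 0
#' @export
relative_se <- function(coefficients, se) {
  if (length(coefficients) != length(se)) {
    stop("coefficients and se must have equal length", call. = FALSE)
  }
  out <- 100 * abs(se / coefficients)
  out[coefficients == 0] <- NA_real_
  out
}
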