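# Avenue II: stability selection by repeated cross-validated elastic-net
# regression. For each repeat a fresh fold assignment is drawn, the penalty
# is tuned by CV over a fixed lambda path, the model is refit on all data at
# the optimal penalty, and the taxa with nonzero coefficients are recorded.
# A taxon's occurrence is the percentage of repeats in which it was selected.

#' Elastic-net stability-selection settings
#'
#' @param alpha elastic-net mixing parameter in (0, 1]; 1 is the lasso
#' @param n_folds number of CV folds (typically 3, 5, 8 or 15)
#' @param n_repeats number of repeated fold assignments; the default 1000
#'   gives 0.1% occurrence granularity
#' @param seed RNG seed for the fold draws
#' @param lambda optional decreasing penalty path; `NULL` lets glmnet derive
#'   one from the full data
#' @param nlambda path length when `lambda` is auto-derived
#' @return an object of class `en_settings`
#' @export
en_settings <- function(alpha = 1, n_folds = 5L, n_repeats = 1000L,
                        seed = 1L, lambda = NULL, nlambda = 50L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("alpha must lie in (0, 1]", call. = FALSE)
  }
  n_folds <- stopifnot_scalar_count(n_folds, "n_folds", min = 2L)
  n_repeats <- stopifnot_scalar_count(n_repeats, "n_repeats")
  if (!is.null(lambda) && (any(lambda <= 0) || is.unsorted(rev(lambda)))) {
    stop("lambda must be a decreasing positive path", call. = FALSE)
  }
  structure(list(alpha = alpha, n_folds = n_folds, n_repeats = n_repeats,
                 seed = as.integer(seed), lambda = lambda,
                 nlambda = as.integer(nlambda)),
            class = "en_settings")
}

# Fast linear prediction over a whole glmnet path.
path_predict <- function(fit, newx) {
  as.matrix(newx %*% fit$beta) +
    matrix(fit$a0, nrow(newx), length(fit$a0), byrow = TRUE)
}

#' Run repeated cross-validated elastic-net selection for one response
#'
#' @param X a [predictor_matrix()] or matrix of predictors
#' @param y numeric response
#' @param settings an [en_settings()]
#' @return named numeric vector of occurrence percentages in `[0, 100]`,
#'   one per taxon
#' @export
run_selection <- function(X, y, settings = en_settings()) {
  stopifnot(inherits(settings, "en_settings"))
  x <- as_design(X)
  n <- nrow(x)
  p <- ncol(x)
  if (length(y) != n) stop("y length mismatch", call. = FALSE)
  if (settings$n_folds > n) {
    stop("degenerate CV folds: more folds than samples", call. = FALSE)
  }
  occ <- stats::setNames(numeric(p), colnames(x))
  if (stats::sd(y) == 0) return(occ)  # nothing can ever be selected

  lam <- settings$lambda %||%
    glmnet::glmnet(x, y, alpha = settings$alpha,
                   nlambda = settings$nlambda)$lambda
  nlam <- length(lam)
  # tight convergence so the recorded nonzero pattern does not depend on
  # numerically razor-edge coordinate-descent stops (e.g. column order)
  full_fit <- glmnet::glmnet(x, y, alpha = settings$alpha, lambda = lam,
                             thresh = 1e-12)
  beta_nonzero <- as.matrix(full_fit$beta != 0)

  k <- settings$n_folds
  counts <- numeric(p)
  set.seed(settings$seed)
  for (rep_i in seq_len(settings$n_repeats)) {
    fid <- sample(rep_len(seq_len(k), n))
    mse <- matrix(NA_real_, k, nlam)
    for (f in seq_len(k)) {
      test <- fid == f
      fit <- glmnet::glmnet(x[!test, , drop = FALSE], y[!test],
                            alpha = settings$alpha, lambda = lam)
      pr <- path_predict(fit, x[test, , drop = FALSE])
      err <- (y[test] - pr)^2
      mse[f, seq_len(ncol(pr))] <- colMeans(err)
    }
    ibest <- which.min(colMeans(mse))
    counts <- counts + beta_nonzero[, ibest]
  }
  occ[] <- 100 * counts / settings$n_repeats
  occ
}

#' Occurrence table over both responses
#'
#' Runs [run_selection()] for the BMI-change and the relative-weight-loss
#' response (with decorrelated seeds derived from `settings$seed`).
#'
#' @inheritParams run_selection
#' @param rwl relative weight loss response
#' @param dbmi BMI-change response
#' @return data.frame `taxon_id`, `occurrence_dbmi`, `occurrence_rwl`
#' @export
occurrence_table <- function(X, rwl, dbmi, settings = en_settings()) {
  s_rwl <- settings
  s_dbmi <- settings
  s_rwl$seed <- derive_seed(settings$seed, 0)
  s_dbmi$seed <- derive_seed(settings$seed, 10007)
  o_rwl <- run_selection(X, rwl, s_rwl)
  o_dbmi <- run_selection(X, dbmi, s_dbmi)
  data.frame(taxon_id = names(o_rwl), occurrence_dbmi = as.numeric(o_dbmi),
             occurrence_rwl = as.numeric(o_rwl), stringsAsFactors = FALSE)
}

#' Filter occurrence candidates
#'
#' Keeps taxa whose occurrence for at least one response reaches the
#' threshold (default 1% over all repeats), sorted by the larger of the two
#' occurrences, descending.
#'
#' @param occ data.frame from [occurrence_table()]
#' @param threshold minimum occurrence in percent
#' @return filtered, sorted data.frame with an extra `occurrence_max` column
#' @export
filter_candidates <- function(occ, threshold = 1) {
  stopifnot(all(c("taxon_id", "occurrence_dbmi", "occurrence_rwl") %in%
                  names(occ)))
  occ$occurrence_max <- pmax(occ$occurrence_dbmi, occ$occurrence_rwl)
  out <- occ[occ$occurrence_max >= threshold, , drop = FALSE]
  out[order(-out$occurrence_max, out$taxon_id), , drop = FALSE]
}

#' Sweep the settings grid
#'
#' Evaluates the occurrence table over a grid of mixing parameters and fold
#' counts, reporting each cell separately.
#'
#' @inheritParams occurrence_table
#' @param alphas mixing parameters to sweep
#' @param folds fold counts to sweep
#' @param n_repeats repeats per cell
#' @param seed base seed; each cell gets a derived seed
#' @return long data.frame with columns `alpha`, `n_folds`, `taxon_id`,
#'   `occurrence_dbmi`, `occurrence_rwl`
#' @export
selection_grid <- function(X, rwl, dbmi, alphas = c(0.25, 0.5, 0.75, 1),
                           folds = c(3, 5, 8, 15), n_repeats = 1000L,
                           seed = 1L) {
  cells <- expand.grid(alpha = alphas, n_folds = folds)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    st <- en_settings(alpha = cells$alpha[i], n_folds = cells$n_folds[i],
                      n_repeats = n_repeats,
                      seed = derive_seed(seed, 977L * i))
    tab <- occurrence_table(X, rwl, dbmi, st)
    out[[i]] <- cbind(alpha = cells$alpha[i], n_folds = cells$n_folds[i], tab)
  }
  do.call(rbind, out)
}
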