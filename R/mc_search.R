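# Avenue III: Monte-Carlo search over multiple linear regression models.
# A large pool of random term subsets is fitted by OLS and scored by AICc;
# per-taxon importance is a weighted combination of three components
# (membership in the best models, Akaike-weighted support, and coefficient
# sign stability), normalized so the best taxon of each stage scores 1.
# The candidate list is then iteratively reduced along a schedule, re-running
# the search on the survivors.

#' Monte-Carlo model-search settings
#'
#' @param n_models number of distinct term subsets sampled per stage
#' @param max_terms largest model size sampled; sizes are uniform on
#'   `1..max_terms`
#' @param weights length-3 nonnegative weights `(A, B, C)` summing to 1 for
#'   the three index components (see [compute_index()])
#' @param schedule strictly decreasing list sizes, starting at the full list
#'   and ending at the final list size (e.g. `c(102, 44, 23, 15, 7)`)
#' @param seed RNG seed
#' @param top_frac fraction of the pool counted as "best models" for
#'   component A (default 5%)
#' @param rss_floor lower bound applied to residual sums of squares so that
#'   exact fits yield finite AICc
#' @return an object of class `mc_settings`
#' @export
mc_settings <- function(n_models = 1e5, max_terms = 4L,
                        weights = c(A = 0.6, B = 0.2, C = 0.2),
                        schedule = NULL, seed = 1L, top_frac = 0.05,
                        rss_floor = 1e-12) {
  n_models <- stopifnot_scalar_count(n_models, "n_models")
  max_terms <- stopifnot_scalar_count(max_terms, "max_terms")
  weights <- as.numeric(weights)
  if (length(weights) != 3L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be 3 nonnegative values summing to 1", call. = FALSE)
  }
  if (!is.null(schedule)) {
    schedule <- as.integer(schedule)
    if (any(diff(schedule) >= 0) || any(schedule < 1)) {
      stop("schedule must be strictly decreasing positive sizes",
           call. = FALSE)
    }
  }
  stopifnot(top_frac > 0, top_frac <= 1, rss_floor > 0)
  structure(list(n_models = n_models, max_terms = as.integer(max_terms),
                 weights = weights, schedule = schedule,
                 seed = as.integer(seed), top_frac = top_frac,
                 rss_floor = rss_floor),
            class = "mc_settings")
}

# Corrected Akaike information criterion. The parameter count includes the
# intercept and the error variance, so a model with m terms has k = m + 2
# (a 4-term model at n = 15 has k = 6).
aicc_from_rss <- function(rss, n, n_terms) {
  k <- n_terms + 2
  if (n - k - 1 <= 0) return(Inf)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Ordinary least squares fit with AICc
#'
#' Fits `y ~ X_subset` with an intercept and reports coefficients, standard
#' errors, residual sum of squares, R-squared statistics and the
#' small-sample AICc. The AICc parameter count includes the intercept and
#' the error variance (a 4-term model has k = 6).
#'
#' @param X_subset design matrix (columns are the model terms, no intercept)
#' @param y response vector
#' @param rss_floor lower bound for the RSS entering the AICc, guarding
#'   exact fits (applied with a warning)
#' @return object of class `ols_fit`: list with `coefficients`, `se`,
#'   `rss`, `aicc`, `k`, `r2`, `adj_r2`, `fitted`, `n`, `terms`
#' @export
fit_ols <- function(X_subset, y, rss_floor = 1e-12) {
  X_subset <- as.matrix(X_subset)
  n <- length(y)
  m <- ncol(X_subset)
  if (nrow(X_subset) != n) stop("dimension mismatch", call. = FALSE)
  if (m + 1 >= n) stop("more parameters than samples support", call. = FALSE)
  Xd <- cbind(`(Intercept)` = 1, X_subset)
  fit <- stats::lm.fit(Xd, y)
  if (any(is.na(fit$coefficients))) {
    bad <- names(fit$coefficients)[is.na(fit$coefficients)]
    stop("singular design; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  res <- fit$residuals
  rss <- sum(res^2)
  if (rss < rss_floor) {
    warning("residual sum of squares below floor; AICc computed at the floor",
            call. = FALSE)
    rss_eff <- rss_floor
  } else {
    rss_eff <- rss
  }
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - m - 1)
  sigma2 <- rss / (n - m - 1)
  XtX_inv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(diag(XtX_inv) * sigma2)
  names(se) <- names(fit$coefficients)
  structure(
    list(coefficients = fit$coefficients, se = se, rss = rss,
         aicc = aicc_from_rss(rss_eff, n, m), k = m + 2, r2 = r2,
         adj_r2 = adj_r2, fitted = as.numeric(Xd %*% fit$coefficients),
         n = n, terms = colnames(X_subset)),
    class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("<ols_fit> %d term(s), AICc %.2f, adj R2 %.3f\n",
              length(x$terms), x$aicc, x$adj_r2))
  print(round(cbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}

# Enumerate all subsets of sizes 1..max_terms as a 0-padded index matrix.
enumerate_subsets <- function(p, max_terms) {
  out <- lapply(seq_len(min(max_terms, p)), function(k) {
    cmb <- utils::combn(p, k)
    rbind(cmb, matrix(0L, max_terms - k, ncol(cmb)))
  })
  t(do.call(cbind, out))
}

#' Sample a pool of linear models
#'
#' Draws `n_models` distinct term subsets (sizes uniform on
#' `1..max_terms`, subsets uniform within size), fits each by OLS and
#' records terms, AICc and coefficient signs. When the total number of
#' subsets does not exceed `n_models` the pool is the exhaustive
#' enumeration. Duplicate draws are rejected, with a cap of
#' `50 * n_models` proposals.
#'
#' @param X a [predictor_matrix()] or matrix; columns restricted to `terms`
#' @param y response vector
#' @param terms candidate term names (default: all columns of `X`)
#' @param settings an [mc_settings()]
#' @return object of class `mc_pool`: list with `terms`, integer matrix
#'   `models` (rows are subsets, 0-padded), `aicc`, `signs`, `n_samples`
#' @export
sample_models <- function(X, y, terms = NULL, settings = mc_settings()) {
  stopifnot(inherits(settings, "mc_settings"))
  x <- as_design(X)
  terms <- terms %||% colnames(x)
  if (!length(terms)) stop("need at least one term", call. = FALSE)
  if (!all(terms %in% colnames(x))) stop("unknown terms", call. = FALSE)
  x <- x[, terms, drop = FALSE]
  p <- length(terms)
  max_terms <- min(settings$max_terms, p)
  if (settings$max_terms > p) {
    max_terms <- p  # cannot sample models larger than the term pool
  }
  n <- length(y)
  total <- sum(choose(p, seq_len(max_terms)))

  set.seed(settings$seed)
  if (total <= settings$n_models) {
    models <- enumerate_subsets(p, max_terms)
  } else {
    models <- matrix(0L, settings$n_models, max_terms)
    seen <- new.env(hash = TRUE, parent = emptyenv())
    got <- 0L
    draws <- 0L
    cap <- 50L * settings$n_models
    while (got < settings$n_models && draws < cap) {
      draws <- draws + 1L
      k <- sample.int(max_terms, 1L)
      idx <- sort(sample.int(p, k))
      key <- paste(idx, collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      got <- got + 1L
      models[got, seq_len(k)] <- idx
    }
    models <- models[seq_len(got), , drop = FALSE]
  }

  nm <- nrow(models)
  aicc <- numeric(nm)
  signs <- matrix(0, nm, max_terms)
  keep <- rep(TRUE, nm)
  for (i in seq_len(nm)) {
    idx <- models[i, ]
    idx <- idx[idx > 0L]
    m <- length(idx)
    if (m + 2 >= n) { keep[i] <- FALSE; next }
    f <- stats::lm.fit(cbind(1, x[, idx, drop = FALSE]), y)
    cf <- f$coefficients
    if (any(is.na(cf))) { keep[i] <- FALSE; next }  # singular subset
    rss <- max(sum(f$residuals^2), settings$rss_floor)
    aicc[i] <- aicc_from_rss(rss, n, m)
    signs[i, seq_len(m)] <- sign(cf[-1])
  }
  if (!all(keep)) {
    models <- models[keep, , drop = FALSE]
    aicc <- aicc[keep]
    signs <- signs[keep, , drop = FALSE]
  }
  structure(list(terms = terms, models = models, aicc = aicc, signs = signs,
                 n_samples = n, settings = settings),
            class = "mc_pool")
}

#' @export
print.mc_pool <- function(x, ...) {
  cat(sprintf("<mc_pool> %d models over %d terms (max size %d)\n",
              nrow(x$models), length(x$terms), ncol(x$models)))
  invisible(x)
}

scale01 <- function(x) {
  rng <- range(x)
  if (diff(rng) <= 0) return(rep(1, length(x)))
  (x - rng[1]) / diff(rng)
}

#' Weighted per-taxon importance index
#'
#' Aggregates a model pool into one importance value per taxon:
#' * **A** — frequency of the taxon among the best `top_frac` (default 5%)
#'   of pool models by AICc;
#' * **B** — mean Akaike weight (`w_i = exp(-dAICc/2)`, normalized over the
#'   pool) of the models containing the taxon;
#' * **C** — coefficient sign consistency (fraction of containing models
#'   carrying the modal sign) multiplied by the taxon's selection frequency
#'   in the full pool.
#'
#' Each component is min-max scaled to `[0, 1]`, combined with the
#' configured weights, and the result divided by the stage maximum so the
#' best taxon scores exactly 1.
#'
#' @param pool an `mc_pool` from [sample_models()]
#' @param settings an [mc_settings()]; defaults to the pool's own settings
#' @return data.frame `taxon_id`, `index`, `rank` (1 = most important,
#'   average ranks for ties), sorted by rank
#' @export
compute_index <- function(pool, settings = pool$settings) {
  stopifnot(inherits(pool, "mc_pool"))
  p <- length(pool$terms)
  nm <- nrow(pool$models)
  if (nm == 0L) stop("empty model pool", call. = FALSE)

  flat_idx <- as.vector(pool$models)
  flat_model <- as.vector(row(pool$models))
  flat_sign <- as.vector(pool$signs)
  mask <- flat_idx > 0L
  flat_idx <- flat_idx[mask]
  flat_model <- flat_model[mask]
  flat_sign <- flat_sign[mask]

  cnt <- tabulate(flat_idx, p)

  n_best <- max(1L, ceiling(settings$top_frac * nm))
  best_models <- order(pool$aicc)[seq_len(n_best)]
  in_best <- flat_model %in% best_models
  A <- tabulate(flat_idx[in_best], p) / n_best

  w <- exp(-(pool$aicc - min(pool$aicc)) / 2)
  w <- w / sum(w)
  sum_w <- rep(0, p)
  agg <- rowsum(w[flat_model], flat_idx)
  sum_w[as.integer(rownames(agg))] <- agg[, 1]
  B <- ifelse(cnt > 0, sum_w / cnt, 0)

  pos <- rep(0, p)
  agg_pos <- rowsum(as.numeric(flat_sign > 0), flat_idx)
  pos[as.integer(rownames(agg_pos))] <- agg_pos[, 1]
  neg <- cnt - pos
  modal_frac <- ifelse(cnt > 0, pmax(pos, neg) / cnt, 0)
  C <- modal_frac * cnt / nm

  wts <- settings$weights
  raw <- wts[1] * scale01(A) + wts[2] * scale01(B) + wts[3] * scale01(C)
  mx <- max(raw)
  index <- if (mx > 0) raw / mx else rep(1, p)
  out <- data.frame(taxon_id = pool$terms, index = index,
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$index, ties.method = "average")
  out[order(out$rank, out$taxon_id), , drop = FALSE]
}

#' Iterative Monte-Carlo list reduction
#'
#' Runs the model search on the full term list, then repeatedly keeps the
#' top-m taxa by index for each m in the reduction schedule, re-running the
#' search on the survivors. The first schedule entry must equal the size of
#' the starting list.
#'
#' @param X a [predictor_matrix()] or matrix
#' @param y response vector
#' @param settings an [mc_settings()]; its `schedule` must be set
#' @param terms starting term list (default: all columns)
#' @return object of class `mc_reduction`: list with `stages` (one index
#'   table per schedule entry, named by list size) and `final_terms`
#' @export
reduce_and_iterate <- function(X, y, settings, terms = NULL) {
  stopifnot(inherits(settings, "mc_settings"))
  x <- as_design(X)
  terms <- terms %||% colnames(x)
  schedule <- settings$schedule
  if (is.null(schedule)) stop("settings$schedule is not set", call. = FALSE)
  if (schedule[1] != length(terms)) {
    stop(sprintf("schedule starts at %d but the term list has %d entries",
                 schedule[1], length(terms)), call. = FALSE)
  }
  stages <- vector("list", length(schedule))
  names(stages) <- as.character(schedule)
  current <- terms
  for (t in seq_along(schedule)) {
    m <- schedule[t]
    if (m > length(current)) {
      stop("schedule value exceeds the current list size", call. = FALSE)
    }
    if (t > 1L) current <- stages[[t - 1L]]$taxon_id[seq_len(m)]
    st <- settings
    st$seed <- derive_seed(settings$seed, 131L * (t - 1L))
    pool <- sample_models(x, y, terms = current, settings = st)
    stages[[t]] <- compute_index(pool, st)
  }
  structure(list(stages = stages,
                 final_terms = stages[[length(stages)]]$taxon_id,
                 schedule = schedule),
            class = "mc_reduction")
}

#' @export
print.mc_reduction <- function(x, ...) {
  cat(sprintf("<mc_reduction> stages: %s; final list: %s\n",
              paste(x$schedule, collapse = " -> "),
              paste(x$final_terms, collapse = ", ")))
  invisible(x)
}

#' Average Monte-Carlo ranks across runs
#'
#' Combines several reduction runs (e.g. two component weightings, possibly
#' for both responses) into per-taxon average ranks on the full list and on
#' the final list. A taxon absent from every final list gets `NA` (a missing
#' marker, not an imputed rank); a taxon absent from some final lists is
#' averaged over the lists that contain it.
#'
#' @param runs list of `mc_reduction` objects sharing the same full term
#'   list
#' @return data.frame `taxon_id`, `avg_rank_full`, `avg_rank_final`
#' @export
average_ranks <- function(runs) {
  if (inherits(runs, "mc_reduction")) runs <- list(runs)
  stopifnot(length(runs) >= 1L,
            all(vapply(runs, inherits, logical(1), "mc_reduction")))
  universe <- runs[[1L]]$stages[[1L]]$taxon_id
  full_ranks <- vapply(runs, function(r) {
    tab <- r$stages[[1L]]
    tab$rank[match(universe, tab$taxon_id)]
  }, numeric(length(universe)))
  final_ranks <- vapply(runs, function(r) {
    tab <- r$stages[[length(r$stages)]]
    tab$rank[match(universe, tab$taxon_id)]
  }, numeric(length(universe)))
  full_ranks <- matrix(full_ranks, nrow = length(universe))
  final_ranks <- matrix(final_ranks, nrow = length(universe))
  avg_final <- rowMeans(final_ranks, na.rm = TRUE)
  avg_final[is.nan(avg_final)] <- NA_real_
  data.frame(taxon_id = universe,
             avg_rank_full = rowMeans(full_ranks),
             avg_rank_final = avg_final,
             stringsAsFactors = FALSE)
}
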