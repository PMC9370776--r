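# Compositional ordination and group comparisons: centered log-ratio
# transform, PCA, Euclidean PERMANOVA (implemented from the distance-matrix
# decomposition so the permutation scheme is fully seeded), Z-scores, and
# Mann-Whitney tests with Benjamini-Hochberg FDR control.

#' Centered log-ratio transform
#'
#' Per sample (row): `log(x + delta) - mean(log(x + delta))`. The default
#' pseudocount is half the smallest nonzero value in the table and is only
#' applied when zeros are present.
#'
#' @param proportions nonnegative matrix (samples x taxa), rows ideally
#'   closed to 1 (the clr is invariant to row scaling)
#' @param pseudocount value added before taking logs; `NULL` picks the
#'   default above
#' @return matrix of the same shape whose rows sum to 0
#' @export
clr_transform <- function(proportions, pseudocount = NULL) {
  x <- as_design(proportions)
  if (any(x < 0)) stop("negative proportions", call. = FALSE)
  has_zero <- any(x == 0)
  if (is.null(pseudocount)) {
    pseudocount <- if (has_zero) min(x[x > 0]) / 2 else 0
  }
  if (has_zero && pseudocount <= 0) {
    stop("zeros present: a positive pseudocount is required", call. = FALSE)
  }
  lx <- log(x + pseudocount)
  sweep(lx, 1, rowMeans(lx), "-")
}

# Within-group sum of squared distances for a squared distance matrix.
ss_within <- function(d2, groups) {
  total <- 0
  for (g in unique(groups)) {
    idx <- groups == g
    total <- total + sum(d2[idx, idx]) / (2 * sum(idx))
  }
  total
}

#' Permutational multivariate analysis of variance
#'
#' One-factor PERMANOVA on a distance matrix: the pseudo-F statistic is
#' computed from the partition of squared inter-point distances into
#' between- and within-group sums, and its significance from seeded label
#' permutations, `p = (1 + #{F_perm >= F_obs}) / (1 + n_permutations)`.
#'
#' @param d distance matrix (`dist` or square symmetric matrix)
#' @param groups group labels, at least 2 levels with at least 2 members
#'   each
#' @param n_permutations number of label permutations (default 999)
#' @param seed RNG seed for the permutations
#' @return object of class `permanova`: list with `pseudo_F`, `p_value`,
#'   `ss_between`, `ss_within`, `df`, `n_permutations`, `seed`
#' @export
permanova <- function(d, groups, n_permutations = 999L, seed = 1L) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (ncol(d) != n || any(abs(d - t(d)) > 1e-8)) {
    stop("d must be a square symmetric distance matrix", call. = FALSE)
  }
  groups <- as.character(groups)
  if (length(groups) != n) stop("groups length mismatch", call. = FALSE)
  sizes <- table(groups)
  if (length(sizes) < 2L || any(sizes < 2L)) {
    stop("need at least 2 groups with at least 2 members each",
         call. = FALSE)
  }
  a <- length(sizes)
  d2 <- d^2
  sst <- sum(d2) / (2 * n)
  pseudo_f <- function(g) {
    ssw <- ss_within(d2, g)
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- pseudo_f(groups)
  set.seed(seed)
  f_perm <- vapply(seq_len(n_permutations),
                   function(i) pseudo_f(sample(groups)), numeric(1))
  p <- (1 + sum(f_perm >= f_obs)) / (1 + n_permutations)
  ssw_obs <- ss_within(d2, groups)
  structure(list(pseudo_F = f_obs, p_value = p,
                 ss_between = sst - ssw_obs, ss_within = ssw_obs,
                 df = c(between = a - 1, within = n - a),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("<permanova> pseudo-F = %.3f (df %d, %d), p = %.4g (%d permutations)\n",
              x$pseudo_F, x$df[1], x$df[2], x$p_value, x$n_permutations))
  invisible(x)
}

#' Per-taxon Mann-Whitney tests with FDR control
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per taxon between two
#' groups, exact when there are no ties, with Benjamini-Hochberg adjusted
#' q-values; rows with q below `flag_q` (default 0.1) are flagged for
#' display.
#'
#' @param values matrix (samples x taxa), e.g. a clr matrix
#' @param groups two-level group labels
#' @param flag_q q-value display threshold
#' @return data.frame `taxon_id`, `U`, `p`, `q`, `flagged`
#' @export
groupwise_tests <- function(values, groups, flag_q = 0.1) {
  x <- as_design(values)
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L) stop("need exactly two groups", call. = FALSE)
  i1 <- groups == lv[1]
  res <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    if (length(unique(v)) == 1L) {
      warning("all-tied taxon: ", colnames(x)[j], call. = FALSE)
      return(c(U = sum(i1) * sum(!i1) / 2, p = 1))
    }
    wt <- suppressWarnings(stats::wilcox.test(v[i1], v[!i1]))
    c(U = unname(wt$statistic), p = wt$p.value)
  }, numeric(2))
  out <- data.frame(taxon_id = colnames(x), U = res[1, ], p = res[2, ],
                    stringsAsFactors = FALSE)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$flagged <- out$q < flag_q
  out[order(out$q, out$p, out$taxon_id), , drop = FALSE]
}

#' Z-scores per taxon
#'
#' Standardizes each taxon (column) across samples using the sample
#' (n - 1 denominator) standard deviation. Constant taxa become all-zero
#' columns with a warning.
#'
#' @param values matrix (samples x taxa)
#' @return matrix of Z-scores
#' @export
zscore <- function(values) {
  x <- as_design(values)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant taxon column(s) set to 0",
            call. = FALSE)
    sds[sds == 0] <- 1
  }
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Principal component analysis of a (clr) submatrix
#'
#' Column-centered PCA of the samples-by-taxa matrix; with clr input the
#' inter-sample distances in score space are the Euclidean clr
#' (Aitchison) distances.
#'
#' @param values matrix (samples x taxa), typically the clr matrix
#'   restricted to the selected predictive taxa
#' @return list with `scores` (samples x components), `loadings`,
#'   `var_explained` (fractions summing to 1)
#' @export
pca_scores <- function(values) {
  x <- as_design(values)
  if (ncol(x) < 2L) stop("need at least 2 taxa", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, var_explained = ve)
}
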