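# Best-subset k-term models, cross-validated R2, and classification.

test_that("best_k_term_models matches the enumeration oracle", {
  d <- random_design(15, 8, seed = 1)
  y <- 2 + 1.5 * d$x[, 2] - d$x[, 5] + rnorm(15, sd = 0.5)
  models <- best_k_term_models(d$x, y, k_range = 1:4)
  oracle <- enumerate_best(d$x, y, 4)
  for (k in 1:4) {
    expect_setequal(models[[paste0("k", k)]]$terms, oracle[[k]]$terms)
    expect_equal(models[[paste0("k", k)]]$aicc, oracle[[k]]$aicc,
                 tolerance = 1e-10)
  }
  # RSS of the best model is nonincreasing in k
  rss <- vapply(models, `[[`, numeric(1), "rss")
  expect_true(all(diff(rss) <= 1e-9))
})

test_that("the best 1-term model is the top-|r| taxon", {
  # provable: for k = 1, RSS = (1 - r^2) * TSS, so AICc ranks by |r|
  d <- random_design(15, 6, seed = 2)
  y <- d$x[, 3] + rnorm(15)
  sc <- correlate_all(d$x, y)
  m1 <- best_k_term_models(d$x, y, k_range = 1)$k1
  expect_equal(m1$terms, sc$taxon_id[1])
})

test_that("cv_r2 is 1 for noiseless linear responses and LOO is deterministic", {
  d <- random_design(15, 4, seed = 3)
  y <- 1 + d$x[, 1] - 2 * d$x[, 2]
  expect_equal(cv_r2(d$x, y, c("v01", "v02"), n_folds = 5, n_repeats = 10,
                     seed = 1), 1, tolerance = 1e-9)
  y2 <- 1 + d$x[, 1] + rnorm(15, sd = 2)
  expect_identical(cv_r2(d$x, y2, "v01", n_folds = 15, seed = 1),
                   cv_r2(d$x, y2, "v01", n_folds = 15, seed = 2))
  expect_error(cv_r2(d$x, y, "v01", n_folds = 20), "folds")
})

test_that("cv_r2 is nonpositive in expectation under the null", {
  d <- random_design(15, 3, seed = 4)
  vals <- vapply(1:30, function(s) {
    set.seed(s)
    cv_r2(d$x, rnorm(15), c("v01", "v02"), n_folds = 5, n_repeats = 20,
          seed = s)
  }, numeric(1))
  expect_lt(mean(vals), 0)
})

test_that("stratified folds keep both outcome groups in training sets", {
  fx <- planted_fixture(seed = 5)
  v <- cv_r2(fx$pm, fx$y, fx$planted, n_folds = 5, n_repeats = 20, seed = 1,
             strata = fx$cohort$outcomes$group)
  expect_true(is.finite(v))
  expect_gt(v, 0.5)  # strong planted signal predicts well out of fold
})

test_that("classification follows the threshold conventions", {
  cl <- classify_predictions(c(12, 8, 10, 9), c(15, 5, 8, 12))
  expect_equal(cl$table$label,
               c("correct(+)", "correct(-)", "overpredicted", "underpredicted"))
  expect_equal(cl$tallies$sum_correct + cl$tallies$sum_incorrect, 4)
  # exact predictions are all correct
  all_ok <- classify_predictions(c(15, 2), c(15, 2))
  expect_equal(all_ok$tallies$sum_incorrect, 0)
  # boundary: prediction at the threshold counts as predicted loss
  bnd <- classify_predictions(rep(10, 3), c(1, 2, 3))
  expect_equal(unname(bnd$tallies$counts["overpredicted"]), 3)
  expect_error(classify_predictions(1:3, 1:4), "equal length")
  expect_error(tally_classifications("nonsense"), "unknown label")
})

test_that("relative_se computes percent relative errors", {
  expect_equal(relative_se(2, 0.5), 25)
  expect_equal(relative_se(-4, 0.48), 12)
  expect_true(is.na(relative_se(0, 1)))
  # oracle: matches summary.lm's se/estimate ratio
  d <- random_design(20, 2, seed = 6)
  y <- 3 + 2 * d$x[, 1] + rnorm(20)
  f <- fit_ols(d$x, y)
  sm <- summary(lm(y ~ d$x))$coefficients
  expect_equal(unname(relative_se(f$coefficients, f$se)),
               unname(100 * abs(sm[, 2] / sm[, 1])), tolerance = 1e-8)
})
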