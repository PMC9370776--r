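# Monte-Carlo model search: OLS/AICc core, pool sampling, the weighted
# importance index, iterative reduction, and rank averaging.

test_that("fit_ols matches a direct normal-equations solve", {
  d <- random_design(15, 3, seed = 2)
  beta_true <- c(1, -2, 0.5)
  y <- 2 + d$x %*% beta_true + rnorm(15, sd = 0.3)
  f <- fit_ols(d$x, y)
  Xd <- cbind(1, d$x)
  beta_oracle <- solve(crossprod(Xd), crossprod(Xd, y))
  expect_equal(unname(f$coefficients), as.numeric(beta_oracle),
               tolerance = 1e-8)
  sigma2 <- sum((y - Xd %*% beta_oracle)^2) / (15 - 4)
  se_oracle <- sqrt(diag(solve(crossprod(Xd))) * sigma2)
  expect_equal(unname(f$se), unname(se_oracle), tolerance = 1e-8)
  # agrees with summary.lm
  sm <- summary(lm(y ~ d$x))
  expect_equal(unname(f$se), unname(sm$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(f$adj_r2, sm$adj.r.squared, tolerance = 1e-10)
})

test_that("AICc uses the df convention counting intercept and variance", {
  d <- random_design(15, 4, seed = 3)
  f <- fit_ols(d$x, d$y)
  expect_equal(f$k, 6)  # 4 terms -> df = 6
  k <- 6
  n <- 15
  expect_equal(f$aicc,
               n * log(f$rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1),
               tolerance = 1e-12)
})

test_that("exact fits hit the RSS floor with a warning", {
  d <- random_design(15, 1, seed = 4)
  y <- 1 + 2 * d$x[, 1]
  expect_warning(f <- fit_ols(d$x, y), "floor")
  expect_true(is.finite(f$aicc))
})

test_that("singular designs name the collinear terms", {
  d <- random_design(15, 2, seed = 5)
  x <- cbind(d$x, dup = d$x[, 1])
  expect_error(fit_ols(x, d$y), "dup")
})

test_that("sample_models enumerates exhaustively when feasible", {
  d <- random_design(15, 6, seed = 6)
  st <- mc_settings(n_models = 1000, max_terms = 3, seed = 1)
  pool <- sample_models(d$x, d$y, settings = st)
  expect_equal(nrow(pool$models), 41)  # C(6,1)+C(6,2)+C(6,3)
  keys <- apply(pool$models, 1, paste, collapse = ",")
  expect_false(anyDuplicated(keys) > 0)
})

test_that("sampling below the subset count stays unique and deterministic", {
  d <- random_design(15, 6, seed = 7)
  st <- mc_settings(n_models = 30, max_terms = 3, seed = 3)
  p1 <- sample_models(d$x, d$y, settings = st)
  p2 <- sample_models(d$x, d$y, settings = st)
  expect_identical(p1$models, p2$models)
  expect_equal(nrow(p1$models), 30)
  keys <- apply(p1$models, 1, paste, collapse = ",")
  expect_false(anyDuplicated(keys) > 0)
})

test_that("a single-term pool gets index 1", {
  d <- random_design(15, 3, seed = 8)
  pool <- sample_models(d$x, d$y, terms = "v01",
                        settings = mc_settings(n_models = 10))
  idx <- compute_index(pool)
  expect_equal(idx$index, 1)
  expect_equal(idx$rank, 1)
})

test_that("the index is normalized to max 1 under any weighting", {
  d <- random_design(15, 6, seed = 9)
  pool <- sample_models(d$x, d$y,
                        settings = mc_settings(n_models = 1000, max_terms = 3))
  for (w in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0.45, 0.1, 0.45))) {
    st <- pool$settings
    st$weights <- w
    idx <- compute_index(pool, st)
    expect_equal(max(idx$index), 1)
    expect_true(all(idx$index >= 0))
  }
})

test_that("the index is invariant to taxon order for an exhaustive pool", {
  d <- random_design(15, 6, seed = 10)
  st <- mc_settings(n_models = 1000, max_terms = 3)
  i1 <- compute_index(sample_models(d$x, d$y, settings = st))
  perm <- c(4, 2, 6, 1, 3, 5)
  i2 <- compute_index(sample_models(d$x[, perm], d$y, settings = st))
  m <- match(i1$taxon_id, i2$taxon_id)
  expect_equal(i2$index[m], i1$index, tolerance = 1e-12)
})

test_that("reduce_and_iterate follows the schedule", {
  fx <- planted_fixture(seed = 1)
  st <- mc_settings(n_models = 1500, schedule = c(102, 44, 23, 15, 7),
                    seed = 1)
  mr <- reduce_and_iterate(fx$pm, fx$y, st)
  expect_equal(names(mr$stages), c("102", "44", "23", "15", "7"))
  expect_equal(vapply(mr$stages, nrow, integer(1), USE.NAMES = FALSE),
               c(102L, 44L, 23L, 15L, 7L))
  expect_length(mr$final_terms, 7)
  # no-reduction schedule gives just the full table
  st1 <- mc_settings(n_models = 500, schedule = 102L, seed = 1)
  mr1 <- reduce_and_iterate(fx$pm, fx$y, st1)
  expect_length(mr1$stages, 1)
  # schedule / list-size mismatches are errors
  expect_error(reduce_and_iterate(fx$pm, fx$y,
                                  mc_settings(schedule = c(50, 7))),
               "schedule")
  expect_error(mc_settings(schedule = c(10, 20)), "decreasing")
})

test_that("average_ranks averages across runs and propagates missingness", {
  mk <- function(full_ids, full_rank, final_ids, final_rank) {
    structure(list(stages = list(
      data.frame(taxon_id = full_ids, index = 1, rank = full_rank),
      data.frame(taxon_id = final_ids, index = 1, rank = final_rank)),
      final_terms = final_ids, schedule = c(4L, 2L)),
      class = "mc_reduction")
  }
  ids <- c("a", "b", "c", "d")
  r1 <- mk(ids, c(1, 2, 3, 4), c("a", "b"), c(1, 2))
  r2 <- mk(ids, c(1, 3, 2, 4), c("a", "c"), c(1, 2))
  avg <- average_ranks(list(r1, r2))
  expect_equal(avg$avg_rank_full, c(1, 2.5, 2.5, 4))
  expect_equal(avg$avg_rank_final[avg$taxon_id == "a"], 1)
  # present in one final list only: averaged over that list
  expect_equal(avg$avg_rank_final[avg$taxon_id == "b"], 2)
  expect_true(is.na(avg$avg_rank_final[avg$taxon_id == "d"]))
})

test_that("stronger planted signal never hurts the full-list rank much", {
  # light version of the monotone-signal property
  med_rank <- function(target) {
    ranks <- vapply(1:8, function(s) {
      co <- generate_cohort(cohort_spec(n_taxa_raw = 300, n_planted = 1,
                                       target_abs_corr = target, seed = s))
      pm <- reduce_to_top(co$abundance, 40)
      pool <- sample_models(pm, co$outcomes$rwl_percent,
                            settings = mc_settings(n_models = 2000,
                                                   seed = s))
      idx <- compute_index(pool)
      idx$rank[match(co$planted$taxon_id, idx$taxon_id)]
    }, numeric(1))
    median(ranks)
  }
  expect_lte(med_rank(0.8), med_rank(0.3))
})
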