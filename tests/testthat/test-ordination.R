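# clr transform, PERMANOVA (with vegan as the independent oracle),
# Mann-Whitney group tests with BH control, Z-scores, and PCA.

test_that("clr_transform matches hand computations", {
  # uniform composition maps to zero
  u <- matrix(1 / 4, 2, 4, dimnames = list(NULL, letters[1:4]))
  expect_true(all(clr_transform(u) == 0))
  # hand example: (0.5, 0.25, 0.25)
  x <- matrix(c(0.5, 0.25, 0.25), 1)
  expect_equal(round(as.numeric(clr_transform(x, pseudocount = 0)), 3),
               c(0.462, -0.231, -0.231))
  # rows sum to zero
  set.seed(1)
  p <- matrix(rexp(60), 6)
  p <- p / rowSums(p)
  expect_true(all(abs(rowSums(clr_transform(p))) < 1e-9))
  # permuting taxa permutes clr columns identically
  cl <- clr_transform(p)
  perm <- c(3, 1, 2, 5, 4, 7, 6, 10, 9, 8)
  expect_equal(clr_transform(p[, perm]), cl[, perm])
})

test_that("clr zero handling follows the pseudocount rules", {
  p <- matrix(c(0.5, 0.5, 0, 1), 2, byrow = TRUE)
  expect_error(clr_transform(p, pseudocount = 0), "pseudocount")
  # default pseudocount: half the smallest nonzero value
  expect_equal(clr_transform(p), clr_transform(p, pseudocount = 0.25))
})

test_that("permanova agrees with the vegan oracle", {
  set.seed(3)
  x <- rbind(matrix(rnorm(8 * 5), 8), matrix(rnorm(7 * 5, mean = 1), 7))
  g <- rep(c("PS", "NS"), c(8, 7))
  d <- dist(x)
  ours <- permanova(d, g, n_permutations = 199, seed = 1)
  ref <- vegan::adonis2(d ~ g, permutations = 999)
  expect_equal(ours$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_lt(abs(ours$p_value - ref$`Pr(>F)`[1]), 0.1)
})

test_that("separated clusters give the minimal p-value", {
  set.seed(4)
  x <- rbind(matrix(rnorm(8 * 3, mean = 0, sd = 0.1), 8),
             matrix(rnorm(7 * 3, mean = 10, sd = 0.1), 7))
  g <- rep(c("A", "B"), c(8, 7))
  res <- permanova(dist(x), g, n_permutations = 999, seed = 2)
  expect_equal(res$p_value, 0.001)
})

test_that("permanova is invariant to sample order and validates input", {
  set.seed(5)
  x <- matrix(rnorm(12 * 4), 12)
  g <- rep(c("A", "B"), 6)
  f1 <- permanova(dist(x), g, n_permutations = 49, seed = 1)$pseudo_F
  ord <- sample(12)
  f2 <- permanova(dist(x[ord, ]), g[ord], n_permutations = 49,
                  seed = 1)$pseudo_F
  expect_equal(f1, f2, tolerance = 1e-10)
  expect_error(permanova(dist(x), rep(c("A", "B"), c(11, 1))), "2 members")
  # p-value lower bound
  expect_gte(f1, 0)
})

test_that("groupwise_tests reaches the exact minimal p at full separation", {
  set.seed(6)
  x <- cbind(sep = c(1:8, 101:107) + rnorm(15, sd = 0.01),
             noise = rnorm(15))
  g <- rep(c("PS", "NS"), c(8, 7))
  res <- groupwise_tests(x, g)
  # exact two-sided Mann-Whitney null at n1 = 8, n2 = 7: min p = 2/C(15,7)
  expect_equal(res$p[res$taxon_id == "sep"], 2 / choose(15, 7),
               tolerance = 1e-12)
  # q-values are BH-monotone in p
  expect_true(all(diff(res$q[order(res$p)]) >= -1e-12))
  # all-tied taxon gets p = 1 with a warning
  expect_warning(res2 <- groupwise_tests(cbind(x, flat = rep(1, 15)), g),
                 "all-tied")
  expect_equal(res2$p[res2$taxon_id == "flat"], 1)
})

test_that("BH keeps the null false-rejection rate near nominal", {
  rej <- vapply(1:60, function(s) {
    set.seed(s)
    x <- matrix(rnorm(15 * 30), 15,
                dimnames = list(NULL, paste0("t", 1:30)))
    g <- rep(c("A", "B"), c(8, 7))
    any(groupwise_tests(x, g)$q < 0.05)
  }, logical(1))
  # with all nulls, FDR control bounds the any-rejection rate by ~5%
  expect_lt(mean(rej), 0.15)
})

test_that("zscore standardizes and is affine-invariant", {
  set.seed(7)
  x <- matrix(rnorm(60, 5, 3), 12, dimnames = list(NULL, paste0("t", 1:5)))
  z <- zscore(x)
  expect_equal(unname(colMeans(z)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 5), tolerance = 1e-12)
  expect_equal(zscore(3 * x + 7), z, ignore_attr = TRUE)
  expect_equal(as.numeric(zscore(matrix(1:3, 3))), c(-1, 0, 1))
  expect_warning(zscore(cbind(x, flat = rep(2, 12))), "constant")
})

test_that("pca_scores explains all variance and respects duplicates", {
  set.seed(8)
  x <- matrix(rnorm(50), 10, dimnames = list(NULL, paste0("t", 1:5)))
  x <- rbind(x, x[1, ])  # duplicated sample
  pc <- pca_scores(x)
  expect_equal(sum(pc$var_explained), 1, tolerance = 1e-9)
  expect_equal(pc$scores[1, ], pc$scores[11, ])
  # loadings are orthonormal
  expect_equal(crossprod(pc$loadings), diag(ncol(pc$loadings)),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_error(pca_scores(x[, 1, drop = FALSE]), "2 taxa")
})

test_that("PC1 separates two constructed clusters", {
  set.seed(9)
  x <- rbind(matrix(rnorm(8 * 4, 0, 0.3), 8), matrix(rnorm(7 * 4, 3, 0.3), 7))
  colnames(x) <- paste0("t", 1:4)
  pc1 <- pca_scores(x)$scores[, 1]
  cl <- rep(1:2, c(8, 7))
  # silhouette on the PC1 axis
  sil <- vapply(seq_along(pc1), function(i) {
    a <- mean(abs(pc1[i] - pc1[cl == cl[i]][-match(i, which(cl == cl[i]))]))
    b <- mean(abs(pc1[i] - pc1[cl != cl[i]]))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
})
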