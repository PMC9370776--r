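# Fixtures built in code; no binary data anywhere.

# 2-sample, 5-taxon toy with taxon column sums 10, 5, 3, 1, 1.
toy_table <- function() {
  vals <- rbind(c(5, 2.5, 1.5, 0.5, 0.5),
                c(5, 2.5, 1.5, 0.5, 0.5))
  colnames(vals) <- paste0("t", 1:5)
  rownames(vals) <- c("s1", "s2")
  abundance_table(vals, level = "genus")
}

# Small planted cohort reduced to its top taxa; shared by several tests.
planted_fixture <- function(seed = 1, n_planted = 3, n_keep = 102) {
  co <- generate_cohort(cohort_spec(n_planted = n_planted, seed = seed))
  list(cohort = co,
       pm = reduce_to_top(co$abundance, n_keep),
       y = co$outcomes$rwl_percent,
       planted = co$planted$taxon_id)
}

# Random regression design for OLS / subset-search oracles.
random_design <- function(n = 15, p = 8, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("v%02d", seq_len(p))))
  y <- rnorm(n)
  list(x = x, y = y)
}

# Exhaustive best subset per size by AICc: the independent enumeration
# oracle for the Monte-Carlo search and the k-term model search.
enumerate_best <- function(x, y, max_terms) {
  n <- length(y)
  out <- list()
  for (k in seq_len(max_terms)) {
    combos <- utils::combn(colnames(x), k)
    best <- NULL
    best_aicc <- Inf
    for (j in seq_len(ncol(combos))) {
      sub <- combos[, j]
      f <- stats::lm.fit(cbind(1, x[, sub, drop = FALSE]), y)
      rss <- sum(f$residuals^2)
      kk <- k + 2
      aicc <- n * log(rss / n) + 2 * kk + 2 * kk * (kk + 1) / (n - kk - 1)
      if (aicc < best_aicc) {
        best_aicc <- aicc
        best <- sub
      }
    }
    out[[k]] <- list(terms = best, aicc = best_aicc)
  }
  out
}

# Printed per-patient classification labels for the five published k-term
# models (patients 1-15 in rows).
published_labels <- function() {
  m <- matrix(c(
    "correct(-)", "correct(-)", "correct(-)", "correct(-)", "correct(-)",
    "correct(-)", "correct(-)", "correct(-)", "correct(-)", "correct(-)",
    "underpredicted", "underpredicted", "correct(+)", "correct(+)", "correct(+)",
    "correct(-)", "correct(-)", "correct(-)", "correct(-)", "correct(-)",
    "correct(-)", "correct(-)", "correct(-)", "correct(-)", "correct(-)",
    "correct(+)", "correct(+)", "correct(+)", "correct(+)", "correct(+)",
    "correct(-)", "correct(-)", "correct(-)", "overpredicted", "correct(-)",
    "correct(+)", "correct(+)", "correct(+)", "correct(+)", "correct(+)",
    "correct(+)", "correct(+)", "correct(+)", "correct(+)", "correct(+)",
    "underpredicted", "correct(+)", "correct(+)", "correct(+)", "correct(+)",
    "overpredicted", "correct(-)", "correct(-)", "correct(-)", "correct(-)",
    "underpredicted", "correct(+)", "correct(+)", "underpredicted", "underpredicted",
    "correct(-)", "correct(-)", "correct(-)", "correct(-)", "correct(-)",
    "underpredicted", "underpredicted", "underpredicted", "correct(+)", "correct(+)",
    "correct(+)", "correct(+)", "correct(+)", "correct(+)", "correct(+)"),
    nrow = 15, byrow = TRUE,
    dimnames = list(NULL, paste0("k", 1:5)))
  m
}

# Published fused-score component columns (genus and species candidates).
published_components <- function() {
  genera <- data.frame(
    taxon_id = c("Symbiobacterium", "Megasphaera", "Marvinbryantia",
                 "Alistipes", "Blautia", "Akkermansia", "Pseudoflavonifractor"),
    rank_full = c(2, 1, 3, 5, 4, NA, NA),
    rank_final = c(1, 2, 3, NA, 4, NA, NA),
    en = c(1, 0, 0, 1, 0, 1, 1),
    corr_class = c(1.5, -0.5, 0, 1.5, 0, 1.5, 0.5),
    score = c(15.5, 11.5, 8, 6.5, 6, 4.5, 3.5),
    stringsAsFactors = FALSE)
  species <- data.frame(
    taxon_id = c("Alistipes finegoldii", "Bacteroides caccae",
                 "Roseburia intestinalis", "Akkermansia muciniphila",
                 "Alistipes spHGB5", "Megamonas hypermegale",
                 "Ethanoligenens harbinense", "Bacteroides stercoris"),
    rank_full = c(1, 3, 3, 5, 3, 5, NA, NA),
    rank_final = c(1, 2.5, 2.5, NA, 5.5, 4.5, NA, 5),
    en = c(1, 0, 0, 1, 0, 0, 1, 0),
    corr_class = c(2, -0.5, 0, 1.5, 0, 0, 1, 0),
    score = c(17, 9, 8.5, 6.5, 5.5, 4.5, 4, 2),
    stringsAsFactors = FALSE)
  list(genera = genera, species = species)
}
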