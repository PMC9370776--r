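# Synthetic cohort generator: log-normal compositional abundances with a
# power-law dominance profile, multinomial count sampling, bimodal weight
# loss outcomes, and planted outcome-associated taxa calibrated on the
# closed composition.

#' Specify a synthetic weight-loss cohort
#'
#' Defaults emulate the reference cohort: 15 patients, 8 of them persistently
#' successful with mean relative weight loss (RWL) 18.2% vs 0.2% in the
#' nonsuccess group, and ~1020 genus-level taxa whose mean abundances decay
#' as a power law steep enough that the top ~10% of taxa carry ~99% of the
#' mass.
#'
#' @param n_patients cohort size
#' @param n_taxa_raw number of taxa columns in the raw table
#' @param dominance power-law exponent of the mean-abundance decay (taxon at
#'   abundance rank i has expected share proportional to `i^-dominance`)
#' @param n_planted number of taxa constructed to correlate with the outcome
#' @param target_abs_corr target |Pearson r| between each planted taxon's
#'   closed relative abundance and RWL; recycled to `n_planted`
#' @param planted_signs sign (+1/-1) of each planted correlation with RWL;
#'   recycled to `n_planted`
#' @param rwl_means group mean RWL in percent, `c(PS, NS)`
#' @param rwl_sd within-group RWL standard deviation in percent
#' @param n_ps number of persistent-success patients
#' @param log_sd shared standard deviation of the per-taxon log abundance
#' @param planted_amplitude relative amplitude of the planted response: a
#'   planted taxon's closed share varies around its mean by this fraction
#'   per latent standard deviation (effect size of the planted taxa)
#' @param depth multinomial sequencing depth per sample (assigned reads)
#' @param baseline_bmi_mean,baseline_bmi_sd baseline BMI distribution (kg/m2)
#' @param dbmi_noise_sd noise added to the BMI change (kg/m2)
#' @param level taxonomy level tag for the generated table
#' @param seed integer RNG seed
#' @return an object of class `cohort_spec`
#' @export
cohort_spec <- function(n_patients = 15L, n_taxa_raw = 1020L, dominance = 2,
                        n_planted = 0L, target_abs_corr = 0.6,
                        planted_signs = 1, rwl_means = c(18.2, 0.2),
                        rwl_sd = 3, n_ps = 8L, log_sd = 1,
                        planted_amplitude = 0.3, depth = 1e6,
                        baseline_bmi_mean = 42.4, baseline_bmi_sd = 6,
                        dbmi_noise_sd = 0.5,
                        level = c("genus", "species"), seed = 1L) {
  level <- match.arg(level)
  n_patients <- stopifnot_scalar_count(n_patients, "n_patients", min = 3L)
  n_taxa_raw <- stopifnot_scalar_count(n_taxa_raw, "n_taxa_raw", min = 2L)
  n_planted <- stopifnot_scalar_count(n_planted, "n_planted", min = 0L)
  n_ps <- stopifnot_scalar_count(n_ps, "n_ps", min = 1L)
  if (n_planted > n_taxa_raw) stop("n_planted exceeds n_taxa_raw", call. = FALSE)
  if (n_ps > n_patients) stop("n_ps exceeds n_patients", call. = FALSE)
  target_abs_corr <- rep_len(as.numeric(target_abs_corr), n_planted)
  planted_signs <- rep_len(as.numeric(planted_signs), n_planted)
  if (n_planted > 0) {
    if (any(target_abs_corr < 0 | target_abs_corr > 1)) {
      stop("target_abs_corr values must lie in [0, 1]", call. = FALSE)
    }
    if (any(!planted_signs %in% c(-1, 1))) {
      stop("planted_signs must be +1 or -1", call. = FALSE)
    }
  }
  stopifnot(length(rwl_means) == 2L, rwl_sd > 0, dominance > 0, log_sd > 0,
            planted_amplitude > 0, planted_amplitude < 1, depth >= 1000)
  structure(
    list(n_patients = n_patients, n_taxa_raw = n_taxa_raw,
         dominance = dominance, n_planted = n_planted,
         target_abs_corr = target_abs_corr, planted_signs = planted_signs,
         rwl_means = as.numeric(rwl_means), rwl_sd = rwl_sd, n_ps = n_ps,
         log_sd = log_sd, planted_amplitude = planted_amplitude,
         depth = depth,
         baseline_bmi_mean = baseline_bmi_mean,
         baseline_bmi_sd = baseline_bmi_sd, dbmi_noise_sd = dbmi_noise_sd,
         level = level, seed = as.integer(seed)),
    class = "cohort_spec")
}

# Noise directions for the planted taxa: unit-variance contrasts orthogonal
# to the standardized outcome that sum to zero across the planted set, so the
# outcome lies (on the latent scale) in the span of the planted taxa -- the
# outcome is "built from" the planted taxa plus residual noise, while each
# taxon's marginal correlation is still set individually by its rotation
# weight. With a single planted taxon this degenerates to one orthogonalized
# noise vector.
planted_noise_directions <- function(m, ystd) {
  n <- length(ystd)
  if (m == 0L) return(matrix(numeric(0), n, 0))
  if (m > n - 3L) {
    stop("too many planted taxa for the cohort size", call. = FALSE)
  }
  # orthonormal basis of the subspace orthogonal to the intercept and ystd
  q <- qr.Q(qr(cbind(1, ystd, matrix(stats::rnorm(n * (n - 2L)), n))))
  W <- q[, 3:(n), drop = FALSE] * sqrt(n - 1)  # unit-variance columns
  if (m == 1L) return(W[, 1L, drop = FALSE])
  # m unit vectors in R^(m-1) summing to zero (regular simplex vertices)
  ev <- eigen(diag(m) - 1 / m, symmetric = TRUE)
  C <- ev$vectors[, seq_len(m - 1L), drop = FALSE] / sqrt((m - 1) / m)
  W[, seq_len(m - 1L), drop = FALSE] %*% t(C)
}

# Positions of the planted taxa in the abundance ranking: spread through the
# dominant part of the table so they survive reduction to the top taxa.
planted_positions <- function(n_planted, n_taxa) {
  if (n_planted == 0) return(integer(0))
  hi <- max(n_planted + 4L, min(50L, n_taxa))
  pos <- unique(round(seq(5L, hi, length.out = n_planted)))
  i <- 5L
  while (length(pos) < n_planted) {  # degenerate tiny tables
    cand <- setdiff(seq(2L, n_taxa), pos)
    pos <- c(pos, cand[1L])
    i <- i + 1L
  }
  sort(pos[seq_len(n_planted)])
}

#' Generate a synthetic cohort
#'
#' Draws outcomes per group from a normal model (group labels then re-derived
#' from the 10% RWL rule), latent per-taxon log abundances from a log-normal
#' model with power-law decaying means, closes rows to compositions, injects
#' the planted signal on the closed-proportion scale, and samples counts
#' from a multinomial at the configured depth. Each planted taxon's closed
#' share responds linearly to a rotation between the standardized outcome
#' and a noise contrast; the rotation weight is calibrated by root finding
#' so the taxon attains its target correlation with RWL on the closed
#' composition, and an unattainable target raises an error rather than
#' being clipped. The noise contrasts sum to zero over the planted set, so
#' with several planted taxa the outcome is (up to sampling noise) a linear
#' combination of their relative abundances. The BMI change is an affine
#' transform of RWL (`delta_bmi = -(baseline_bmi/100) * rwl + noise`), so
#' positive weight loss maps to a negative BMI change.
#'
#' @param spec a [cohort_spec()]
#' @return an object of class `synthetic_cohort`: list with elements
#'   `abundance` ([abundance_table()] of counts), `outcomes` (data.frame),
#'   `planted` (data.frame of planted taxon ids and targets) and `spec`
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  p <- spec$n_taxa_raw
  n_ns <- n - spec$n_ps

  rwl <- c(stats::rnorm(spec$n_ps, spec$rwl_means[1], spec$rwl_sd),
           stats::rnorm(n_ns, spec$rwl_means[2], spec$rwl_sd))
  bmi0 <- pmax(stats::rnorm(n, spec$baseline_bmi_mean, spec$baseline_bmi_sd), 25)
  dbmi <- -(bmi0 / 100) * rwl + stats::rnorm(n, 0, spec$dbmi_noise_sd)
  group <- ifelse(rwl >= 10, "PS", "NS")

  mu <- -spec$dominance * log(seq_len(p))
  Z <- matrix(stats::rnorm(n * p), n, p)
  L <- sweep(Z * spec$log_sd, 2, mu, "+")

  P <- exp(L)
  P <- P / rowSums(P)

  # Planted signal enters on the closed-proportion scale: each planted
  # column becomes mean_share * (1 + amplitude * latent), with the latent
  # a rotation between the standardized outcome and a noise contrast. The
  # noise contrasts sum to zero across the planted set, so the outcome is
  # (up to noise) a linear combination of the planted proportions -- the
  # structure a linear selection pipeline assumes -- while each taxon's
  # marginal correlation is calibrated individually by root finding on the
  # re-closed table.
  planted_idx <- planted_positions(spec$n_planted, p)
  ystd <- as.numeric(scale(rwl))
  noise_dirs <- planted_noise_directions(spec$n_planted, ystd)
  if (spec$n_planted > 0) {
    amp <- spec$planted_amplitude  # default keeps shares positive to |latent| ~3.3
    base_share <- colMeans(P)[planted_idx]
    rot <- numeric(spec$n_planted)
    planted_col <- function(j, a) {
      lat <- spec$planted_signs[j] *
        (a * ystd + sqrt(1 - a^2) * noise_dirs[, j])
      base_share[j] * pmax(1 + amp * lat, 0.01)
    }
    reclose <- function(Pmod) Pmod / rowSums(Pmod)
    for (j in seq_len(spec$n_planted)) {
      target <- spec$target_abs_corr[j] * spec$planted_signs[j]
      if (spec$target_abs_corr[j] == 0) next
      realized <- function(a) {
        Pm <- P
        Pm[, planted_idx[j]] <- planted_col(j, a)
        stats::cor(reclose(Pm)[, planted_idx[j]], rwl)
      }
      f <- function(a) realized(a) - target
      a_star <- if (f(-0.5) * f(0.9995) < 0) {
        stats::uniroot(f, c(-0.5, 0.9995), tol = 1e-5)$root
      } else {
        stats::optimize(function(a) f(a)^2, c(-0.5, 0.9995))$minimum
      }
      if (abs(f(a_star)) > 0.05) {
        stop(sprintf(
          "target correlation %.2f for planted taxon %d is unattainable under the current noise model",
          target, planted_idx[j]), call. = FALSE)
      }
      rot[j] <- a_star
      P[, planted_idx[j]] <- planted_col(j, a_star)
    }
    P <- reclose(P)
  }
  counts <- t(vapply(seq_len(n),
                     function(i) stats::rmultinom(1, spec$depth, P[i, ])[, 1],
                     numeric(p)))

  taxon_ids <- sprintf("taxon_%04d", seq_len(p))
  sample_ids <- sprintf("P%02d", seq_len(n))
  dimnames(counts) <- list(sample_ids, taxon_ids)

  outcomes <- data.frame(
    patient_id = sample_ids, group = group,
    rwl_percent = rwl, delta_bmi = dbmi, baseline_bmi = bmi0,
    stringsAsFactors = FALSE)

  planted <- data.frame(
    taxon_id = taxon_ids[planted_idx],
    target_abs_corr = spec$target_abs_corr,
    sign = spec$planted_signs, stringsAsFactors = FALSE)

  structure(
    list(abundance = abundance_table(counts, sample_ids, taxon_ids,
                                     level = spec$level,
                                     is_proportion = FALSE),
         outcomes = outcomes, planted = planted, spec = spec),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d patients (%d PS / %d NS), %d taxa, %d planted\n",
    nrow(x$outcomes), sum(x$outcomes$group == "PS"),
    sum(x$outcomes$group == "NS"), length(x$abundance$taxon_ids),
    nrow(x$planted)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits `abundance.tsv` (first column `sample_id`, one column per taxon),
#' `outcomes.csv`, and `provenance.json` recording the generating spec and
#' seed so the cohort can be regenerated bit-for-bit. Files round-trip
#' losslessly through [load_abundance()] / [load_outcomes()].
#'
#' @param cohort a `synthetic_cohort`
#' @param dir_path output directory (created if missing)
#' @return invisibly, the written file paths
#' @export
write_cohort <- function(cohort, dir_path) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir_path)) {
    ok <- dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", dir_path, call. = FALSE)
  }
  paths <- c(abundance = file.path(dir_path, "abundance.tsv"),
             outcomes = file.path(dir_path, "outcomes.csv"),
             provenance = file.path(dir_path, "provenance.json"))
  ab <- data.frame(sample_id = cohort$abundance$sample_ids,
                   cohort$abundance$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(ab, paths[["abundance"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(cohort$outcomes[, c("patient_id", "group", "rwl_percent",
                                       "delta_bmi")],
                   paths[["outcomes"]], row.names = FALSE, quote = FALSE)
  prov <- c(unclass(cohort$spec),
            list(planted_taxa = cohort$planted$taxon_id))
  jsonlite::write_json(prov, paths[["provenance"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
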