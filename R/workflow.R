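# End-to-end orchestration: one config drives synthetic generation (or file
# input), data reduction, the three selection avenues, score fusion, k-term
# prediction models, and ordination, writing every stage's outputs plus a
# run manifest.

#' Pipeline configuration
#'
#' Exactly one of `spec` (synthetic cohort) or `abundance_path` +
#' `outcomes_path` must be given. Stage settings default to the published
#' analysis choices: lasso (`alpha = 1`) with 5 folds, index weightings
#' (0.6, 0.2, 0.2) and (0.45, 0.10, 0.45), score weights (1, 1, 3, 1) with
#' rank ceiling 7, classification threshold 10, CV with 3/5/8/15 folds.
#'
#' @param spec a [cohort_spec()] for synthetic input, or `NULL`
#' @param abundance_path,outcomes_path input files, or `NULL`
#' @param level taxonomy level
#' @param n_keep number of dominant taxa retained by the reduction
#' @param blacklist taxa removed before reduction (`NULL` = level default)
#' @param en an [en_settings()]
#' @param mc an [mc_settings()]; its schedule may be `NULL`, in which case a
#'   schedule proportional to the published genus schedule is derived from
#'   `n_keep`
#' @param mc_weights2 second component weighting for the Monte-Carlo index
#' @param score a [score_weights()]
#' @param threshold classification threshold (percent relative weight loss)
#' @param dbmi_direction `"loss"` (default) screens taxa against the BMI
#'   *reduction* `-delta_bmi`, so that a success-associated taxon correlates
#'   with the same sign to both responses (the convention of the published
#'   candidate tables); `"change"` screens against the raw BMI change
#' @param cv_folds fold counts for the cross-validated R-squared
#' @param cv_repeats repeated fold assignments per fold count
#' @param k_range model sizes for the best-subset search
#' @param n_permutations PERMANOVA permutations
#' @param seed global seed; per-stage seeds are derived from it
#' @return an object of class `run_config`
#' @export
run_config <- function(spec = NULL, abundance_path = NULL,
                       outcomes_path = NULL, level = c("genus", "species"),
                       n_keep = 102L, blacklist = NULL,
                       en = en_settings(), mc = mc_settings(),
                       mc_weights2 = c(A = 0.45, B = 0.10, C = 0.45),
                       score = score_weights(), threshold = 10,
                       dbmi_direction = c("loss", "change"),
                       cv_folds = c(3, 5, 8, 15), cv_repeats = 200L,
                       k_range = 1:5, n_permutations = 999L, seed = 1L) {
  level <- match.arg(level)
  dbmi_direction <- match.arg(dbmi_direction)
  from_files <- !is.null(abundance_path) || !is.null(outcomes_path)
  if (is.null(spec) == !from_files) {
    stop("provide exactly one of: a cohort spec, or abundance + outcomes paths",
         call. = FALSE)
  }
  if (from_files && (is.null(abundance_path) || is.null(outcomes_path))) {
    stop("both abundance_path and outcomes_path are required", call. = FALSE)
  }
  structure(list(spec = spec, abundance_path = abundance_path,
                 outcomes_path = outcomes_path, level = level,
                 n_keep = as.integer(n_keep), blacklist = blacklist,
                 en = en, mc = mc, mc_weights2 = as.numeric(mc_weights2),
                 score = score, threshold = threshold,
                 dbmi_direction = dbmi_direction,
                 cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(cv_repeats),
                 k_range = as.integer(k_range),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Reduction schedule proportional to the published genus schedule
#'
#' Scales the 102 -> 44 -> 23 -> 15 -> 7 genus schedule to an arbitrary
#' starting list size, dropping duplicates so the result stays strictly
#' decreasing.
#'
#' @param p starting list size
#' @param final_size size of the final list (default 7)
#' @return integer vector of stage sizes
#' @export
default_schedule <- function(p, final_size = 7L) {
  ratios <- c(44, 23, 15) / 102
  mid <- unique(pmax(round(p * ratios), final_size + 1L))
  sched <- unique(c(p, mid[mid < p], final_size))
  as.integer(sched[order(-sched)])
}

#' Run the full discovery and prediction pipeline
#'
#' Executes: input (synthetic or files) -> blacklist + reduction ->
#' correlation screening -> elastic-net occurrence selection -> Monte-Carlo
#' search (two weightings x two responses) -> final score fusion -> best
#' k-term models with cross-validated R-squared and per-patient
#' classification -> clr/PCA/PERMANOVA/group tests on the selected taxa.
#' All stage outputs are written as CSV under `out_dir` together with a
#' `manifest.json`; reruns with an identical config reproduce identical
#' outputs.
#'
#' @param config a [run_config()]
#' @param out_dir output directory, or `NULL` to skip writing files
#' @return invisibly, a list with every stage result
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  if (!is.null(config$spec)) {
    cohort <- generate_cohort(config$spec)
    abundance <- cohort$abundance
    outcomes <- cohort$outcomes
  } else {
    cohort <- NULL
    abundance <- load_abundance(config$abundance_path, config$level)
    outcomes <- load_outcomes(config$outcomes_path)
  }
  rwl <- outcomes$rwl_percent
  dbmi <- outcomes$delta_bmi

  blacklist <- config$blacklist %||%
    intersect(default_blacklist(config$level), abundance$taxon_ids)
  ab <- drop_blacklisted(abundance, blacklist)
  pred <- reduce_to_top(ab, min(config$n_keep, length(ab$taxon_ids)))

  dbmi_screen <- if (config$dbmi_direction == "loss") -dbmi else dbmi
  corr <- screen_taxa(pred, rwl, dbmi_screen)

  en <- config$en
  en$seed <- derive_seed(seed, 101L)
  occ <- occurrence_table(pred, rwl, dbmi, en)
  en_cand <- filter_candidates(occ)

  mc1 <- config$mc
  mc1$schedule <- mc1$schedule %||% default_schedule(ncol(pred$values))
  mc2 <- mc1
  mc2$weights <- config$mc_weights2
  runs <- list()
  responses <- list(rwl = rwl, dbmi = dbmi)
  sets <- list(w1 = mc1, w2 = mc2)
  i <- 0L
  for (rn in names(responses)) {
    for (sn in names(sets)) {
      i <- i + 1L
      st <- sets[[sn]]
      st$seed <- derive_seed(seed, 211L + 53L * i)
      runs[[paste(rn, sn, sep = "_")]] <-
        reduce_and_iterate(pred, responses[[rn]], st)
    }
  }
  ranks <- average_ranks(runs)

  candidates <- build_candidate_table(ranks, en_cand$taxon_id, corr,
                                      config$score)
  final_terms <- candidates$report$taxon_id

  k_range <- config$k_range[config$k_range <= length(final_terms)]
  models <- list()
  cv <- list()
  class_tabs <- list()
  for (rn in names(responses)) {
    y <- responses[[rn]]
    models[[rn]] <- best_k_term_models(pred, y, final_terms, k_range)
    cv[[rn]] <- lapply(models[[rn]], function(m) {
      vapply(config$cv_folds, function(k) {
        cv_r2(pred, y, m$terms, n_folds = k, n_repeats = config$cv_repeats,
              seed = derive_seed(seed, 307L), strata = outcomes$group)
      }, numeric(1)) |> stats::setNames(paste0("folds", config$cv_folds))
    })
  }
  class_tabs <- lapply(models$rwl, function(m) {
    classify_predictions(m$fitted, rwl, config$threshold)
  })

  clr <- clr_transform(pred$values)
  clr_sel <- clr[, final_terms, drop = FALSE]
  ord <- list(
    pca = pca_scores(clr_sel),
    permanova = permanova(stats::dist(clr_sel), outcomes$group,
                          config$n_permutations,
                          seed = derive_seed(seed, 401L)),
    tests = groupwise_tests(clr_sel, outcomes$group))

  result <- list(cohort = cohort, abundance = abundance, outcomes = outcomes,
                 predictors = pred, screening = corr, en_occurrence = occ,
                 en_candidates = en_cand, mc_runs = runs,
                 rank_summary = ranks, candidates = candidates,
                 final_terms = final_terms, models = models, cv_r2 = cv,
                 classification = class_tabs, ordination = ord,
                 config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  invisible(result)
}

write_pipeline_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE,
                     quote = FALSE)
  }
  wcsv(result$screening, "screening.csv")
  wcsv(result$en_occurrence, "en_occurrence.csv")
  wcsv(result$rank_summary, "mc_rank_summary.csv")
  for (rn in names(result$mc_runs)) {
    run <- result$mc_runs[[rn]]
    for (sz in names(run$stages)) {
      wcsv(run$stages[[sz]], sprintf("mc_%s_stage%s.csv", rn, sz))
    }
  }
  wcsv(result$candidates$full, "candidate_table.csv")
  wcsv(result$candidates$report, "candidate_report.csv")

  model_rows <- list()
  for (rn in names(result$models)) {
    for (kn in names(result$models[[rn]])) {
      m <- result$models[[rn]][[kn]]
      cvv <- result$cv_r2[[rn]][[kn]]
      model_rows[[paste(rn, kn)]] <- data.frame(
        response = rn, k = length(m$terms),
        terms = paste(m$terms, collapse = ";"),
        coefficients = paste(signif(m$coefficients, 8), collapse = ";"),
        se = paste(signif(m$se, 8), collapse = ";"),
        relative_se_pct = paste(
          round(relative_se(m$coefficients, m$se), 2), collapse = ";"),
        aicc = m$aicc, adj_r2 = m$adj_r2,
        t(as.matrix(cvv)), stringsAsFactors = FALSE)
    }
  }
  wcsv(do.call(rbind, model_rows), "model_reports.csv")

  cls <- do.call(rbind, lapply(names(result$classification), function(kn) {
    tab <- result$classification[[kn]]$table
    cbind(model = kn, tab)
  }))
  wcsv(cls, "classification.csv")
  wcsv(result$ordination$tests, "group_tests.csv")
  wcsv(data.frame(sample = rownames(result$ordination$pca$scores),
                  result$ordination$pca$scores[, 1:2, drop = FALSE],
                  group = result$outcomes$group), "pca_scores.csv")
  wcsv(data.frame(taxon_id = rownames(result$ordination$pca$loadings),
                  result$ordination$pca$loadings, check.names = FALSE),
       "pca_loadings.csv")

  manifest <- list(
    seed = result$config$seed,
    level = result$config$level,
    n_keep = result$config$n_keep,
    coverage = result$predictors$coverage,
    final_terms = result$final_terms,
    permanova_p = result$ordination$permanova$p_value,
    synthetic = !is.null(result$cohort),
    r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
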