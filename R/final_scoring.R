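# Fusion of the three evidence streams (correlation class, elastic-net
# selection, Monte-Carlo ranks) into a single candidate score per taxon.

#' Final-score weights
#'
#' @param w_full weight of the full-list Monte-Carlo rank term
#' @param w_final weight of the final-list Monte-Carlo rank term
#' @param w_en weight of the elastic-net selection indicator
#' @param w_corr weight of the absolute correlation class
#' @param rank_ceiling constant the ranks are subtracted from; ranks at or
#'   beyond the ceiling contribute 0 (never negative)
#' @param min_score reporting cutoff; taxa below it are kept in the full
#'   output but excluded from the report
#' @return an object of class `score_weights`
#' @export
score_weights <- function(w_full = 1, w_final = 1, w_en = 3, w_corr = 1,
                          rank_ceiling = 7, min_score = 2) {
  w <- c(w_full, w_final, w_en, w_corr)
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("weights must be nonnegative", call. = FALSE)
  }
  structure(list(w_full = w_full, w_final = w_final, w_en = w_en,
                 w_corr = w_corr, rank_ceiling = rank_ceiling,
                 min_score = min_score),
            class = "score_weights")
}

#' Final candidate score
#'
#' `score = w_full * max(0, ceiling - rank_full)
#'        + w_final * max(0, ceiling - rank_final)
#'        + w_en * en_selected + w_corr * |corr_class|`,
#' with a missing (`NA`) rank contributing 0. With the default weights
#' (1, 1, 3, 1) and ceiling 7 this is the published fusion rule.
#'
#' @param rank_full average full-list Monte-Carlo rank (>= 1) or `NA`
#' @param rank_final average final-list Monte-Carlo rank (>= 1) or `NA`
#' @param en_selected 0/1 elastic-net selection indicator
#' @param corr_class signed correlation class (its absolute value enters)
#' @param weights a [score_weights()]
#' @return numeric score vector
#' @export
final_score <- function(rank_full, rank_final, en_selected, corr_class,
                        weights = score_weights()) {
  stopifnot(inherits(weights, "score_weights"))
  n <- max(length(rank_full), length(rank_final), length(en_selected),
           length(corr_class))
  rank_full <- rep_len(rank_full, n)
  rank_final <- rep_len(rank_final, n)
  en_selected <- rep_len(en_selected, n)
  corr_class <- rep_len(corr_class, n)
  if (any(rank_full < 1 | rank_final < 1, na.rm = TRUE)) {
    stop("ranks must be >= 1", call. = FALSE)
  }
  if (any(!en_selected %in% c(0, 1))) {
    stop("en_selected must be 0 or 1", call. = FALSE)
  }
  rank_term <- function(r) {
    out <- pmax(0, weights$rank_ceiling - r)
    out[is.na(out)] <- 0
    out
  }
  weights$w_full * rank_term(rank_full) +
    weights$w_final * rank_term(rank_final) +
    weights$w_en * en_selected +
    weights$w_corr * abs(corr_class)
}

#' Build the fused candidate table
#'
#' Joins the Monte-Carlo rank summary, the elastic-net candidate list and
#' the correlation records over the union of their taxa, computes the final
#' score for every taxon, and splits the result into a report (taxa at or
#' above `min_score`) and the full table.
#'
#' @param rank_summary data.frame from [average_ranks()]
#' @param en_candidates character vector of elastic-net-selected taxon ids
#'   (e.g. `filter_candidates(...)$taxon_id`)
#' @param corr_records data.frame from [screen_taxa()] (needs `taxon_id`,
#'   `corr_class`)
#' @param weights a [score_weights()]
#' @return object of class `candidate_table`: list with data.frames `report`
#'   and `full`, both sorted by decreasing score
#' @export
build_candidate_table <- function(rank_summary, en_candidates, corr_records,
                                  weights = score_weights()) {
  stopifnot(all(c("taxon_id", "avg_rank_full", "avg_rank_final") %in%
                  names(rank_summary)),
            all(c("taxon_id", "corr_class") %in% names(corr_records)))
  if (anyDuplicated(rank_summary$taxon_id) ||
      anyDuplicated(corr_records$taxon_id)) {
    stop("duplicate taxon entries in an evidence stream", call. = FALSE)
  }
  universe <- Reduce(union, list(rank_summary$taxon_id,
                                 as.character(en_candidates),
                                 corr_records$taxon_id))
  i_rank <- match(universe, rank_summary$taxon_id)
  i_corr <- match(universe, corr_records$taxon_id)
  tab <- data.frame(
    taxon_id = universe,
    avg_rank_full = rank_summary$avg_rank_full[i_rank],
    avg_rank_final = rank_summary$avg_rank_final[i_rank],
    en_selected = as.integer(universe %in% en_candidates),
    corr_class = ifelse(is.na(i_corr), 0, corr_records$corr_class[i_corr]),
    stringsAsFactors = FALSE)
  tab$score <- final_score(tab$avg_rank_full, tab$avg_rank_final,
                           tab$en_selected, tab$corr_class, weights)
  tab <- tab[order(-tab$score, tab$taxon_id), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(report = tab[tab$score >= weights$min_score, , drop = FALSE],
                 full = tab, weights = weights),
            class = "candidate_table")
}

#' @export
print.candidate_table <- function(x, ...) {
  cat(sprintf("<candidate_table> %d taxa scored, %d at or above %.1f\n",
              nrow(x$full), nrow(x$report), x$weights$min_score))
  print(x$report, row.names = FALSE)
  invisible(x)
}
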