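# Abundance-table containers, file readers, and the data reduction that
# turns a raw taxa-by-sample table into the regression design.

#' Construct a validated abundance table
#'
#' A taxa-by-sample matrix of raw counts or relative abundances, tagged with
#' the taxonomy level it was binned at. Rows are samples, columns are taxa.
#'
#' @param values numeric matrix, samples in rows, taxa in columns
#' @param sample_ids character vector of sample identifiers (defaults to
#'   rownames of `values`)
#' @param taxon_ids character vector of unique taxon identifiers (defaults to
#'   colnames of `values`)
#' @param level taxonomy level, `"genus"` or `"species"`
#' @param is_proportion logical; `TRUE` when rows are compositions summing
#'   to 1
#' @return an object of class `abundance_table`
#' @export
abundance_table <- function(values, sample_ids = rownames(values),
                            taxon_ids = colnames(values),
                            level = c("genus", "species"),
                            is_proportion = FALSE) {
  level <- match.arg(level)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(taxon_ids)) stop("taxon_ids are required", call. = FALSE)
  sample_ids <- as.character(sample_ids)
  taxon_ids <- as.character(taxon_ids)
  if (length(sample_ids) != nrow(values) || length(taxon_ids) != ncol(values)) {
    stop("id lengths do not match the matrix dimensions", call. = FALSE)
  }
  dup <- taxon_ids[duplicated(taxon_ids)]
  if (length(dup)) {
    stop("duplicate taxon columns: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    cell <- bad[1L, ]
    stop(sprintf(
      "invalid abundance value at sample '%s', taxon '%s' (%s)",
      sample_ids[cell[1L]], taxon_ids[cell[2L]],
      format(values[cell[1L], cell[2L]])), call. = FALSE)
  }
  if (is_proportion) {
    rs <- rowSums(values)
    off <- which(abs(rs - 1) > 1e-6)
    if (length(off)) {
      stop("proportion rows do not sum to 1: sample(s) ",
           paste(sample_ids[off], collapse = ", "), call. = FALSE)
    }
  }
  dimnames(values) <- list(sample_ids, taxon_ids)
  structure(
    list(sample_ids = sample_ids, taxon_ids = taxon_ids, values = values,
         level = level, is_proportion = is_proportion),
    class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d samples x %d taxa (%s level, %s)\n",
              length(x$sample_ids), length(x$taxon_ids), x$level,
              if (x$is_proportion) "proportions" else "counts"))
  invisible(x)
}

#' Construct a predictor matrix
#'
#' The reduced, row-closed proportions matrix used as the regression design,
#' together with the fraction of the original abundance mass it retains.
#'
#' @param values numeric matrix of proportions (samples x retained taxa)
#' @param coverage fraction of the original relative-abundance mass retained,
#'   in (0, 1]
#' @inheritParams abundance_table
#' @return an object of class `predictor_matrix`
#' @export
predictor_matrix <- function(values, sample_ids = rownames(values),
                             taxon_ids = colnames(values), coverage = 1) {
  values <- as.matrix(values)
  if (!is.numeric(coverage) || length(coverage) != 1L ||
      coverage <= 0 || coverage > 1 + 1e-9) {
    stop("coverage must be a single value in (0, 1]", call. = FALSE)
  }
  dimnames(values) <- list(sample_ids, taxon_ids)
  structure(
    list(sample_ids = as.character(sample_ids),
         taxon_ids = as.character(taxon_ids),
         values = values, coverage = min(coverage, 1)),
    class = "predictor_matrix")
}

#' @export
print.predictor_matrix <- function(x, ...) {
  cat(sprintf("<predictor_matrix> %d samples x %d taxa, coverage %.3f\n",
              length(x$sample_ids), length(x$taxon_ids), x$coverage))
  invisible(x)
}

# Coerce predictor_matrix / abundance_table / matrix to a plain design matrix.
as_design <- function(x) {
  if (inherits(x, "predictor_matrix") || inherits(x, "abundance_table")) {
    return(x$values)
  }
  as.matrix(x)
}

#' Read a taxa-by-sample abundance file
#'
#' Reads a TSV (or CSV) file whose first column holds sample identifiers and
#' whose remaining columns are taxa. Whether the body holds counts or
#' proportions is auto-detected from the row sums; ambiguous tables must be
#' disambiguated with `is_proportion`.
#'
#' @param path file path; `.csv` is read comma-separated, anything else
#'   tab-separated
#' @param level taxonomy level tag, `"genus"` or `"species"`
#' @param is_proportion logical or `NULL` (auto-detect)
#' @return an [abundance_table()]
#' @export
load_abundance <- function(path, level = c("genus", "species"),
                           is_proportion = NULL) {
  level <- match.arg(level)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("abundance file needs a sample column plus taxa",
                          call. = FALSE)
  sample_ids <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  if (!all(vapply(body, is.numeric, logical(1)))) {
    stop("non-numeric abundance columns in ", path, call. = FALSE)
  }
  values <- as.matrix(body)
  rownames(values) <- sample_ids
  if (is.null(is_proportion)) {
    rs <- rowSums(values)
    if (all(abs(rs - 1) < 1e-3)) {
      is_proportion <- TRUE
    } else if (all(rs >= 2)) {
      is_proportion <- FALSE
    } else {
      stop("cannot auto-detect counts vs proportions (row sums neither ~1 ",
           "nor clearly counts); pass is_proportion explicitly", call. = FALSE)
    }
  }
  abundance_table(values, sample_ids, colnames(values), level = level,
                  is_proportion = is_proportion)
}

#' Read a per-patient outcomes file
#'
#' Expects a CSV with columns `patient_id`, `group`, `rwl_percent`,
#' `delta_bmi`. Group labels are PS (persistent success, relative weight loss
#' of at least 10%) and NS.
#'
#' @param path CSV file path
#' @param check_groups verify the PS/NS labels against the 10% relative
#'   weight-loss rule
#' @param threshold relative weight-loss threshold (percent) defining
#'   persistent success
#' @return data.frame with the four columns above
#' @export
load_outcomes <- function(path, check_groups = TRUE, threshold = 10) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "group", "rwl_percent", "delta_bmi")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("outcomes file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$group %in% c("PS", "NS"))) {
    stop("group labels must be PS or NS", call. = FALSE)
  }
  if (check_groups) {
    expect <- ifelse(df$rwl_percent >= threshold, "PS", "NS")
    off <- which(expect != df$group)
    if (length(off)) {
      stop("group label inconsistent with the ", threshold,
           "% rule for patient(s): ",
           paste(df$patient_id[off], collapse = ", "), call. = FALSE)
    }
  }
  df[, need]
}

#' Default genus blacklist
#'
#' Three thermophilic genera that do not normally occur in the human gut and
#' are treated as likely read-binning misclassifications; they are removed
#' from genus-level tables before abundance reduction. Species-level tables
#' have an empty default blacklist.
#'
#' @param level taxonomy level
#' @return character vector of taxon names
#' @export
default_blacklist <- function(level = c("genus", "species")) {
  level <- match.arg(level)
  if (level == "genus") {
    c("Caldicellulosiruptor", "Thermaerobacter", "Thermobacillus")
  } else {
    character(0)
  }
}

#' Remove blacklisted taxa
#'
#' @param table an [abundance_table()]
#' @param blacklist taxon names to drop; `NULL` uses [default_blacklist()]
#'   for the table's level
#' @return the table without the blacklisted columns
#' @export
drop_blacklisted <- function(table, blacklist = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  blacklist <- blacklist %||% default_blacklist(table$level)
  if (!length(blacklist)) return(table)
  absent <- setdiff(blacklist, table$taxon_ids)
  if (length(absent)) {
    warning("blacklist entries not present: ", paste(absent, collapse = ", "),
            call. = FALSE)
  }
  keep <- !(table$taxon_ids %in% blacklist)
  if (all(keep)) return(table)
  abundance_table(table$values[, keep, drop = FALSE], table$sample_ids,
                  table$taxon_ids[keep], level = table$level,
                  is_proportion = FALSE)
}

#' Reduce a table to its most abundant taxa
#'
#' Keeps the `n_keep` taxa with the largest mean relative abundance across
#' samples (optionally: largest prevalence), reports the fraction of the
#' original mass they cover, and re-closes each row to proportions over the
#' retained taxa. Ties in the ordering statistic are broken by taxon id.
#'
#' @param table an [abundance_table()] or [predictor_matrix()]
#' @param n_keep number of taxa to retain
#' @param statistic ordering statistic, `"mean"` relative abundance or
#'   `"prevalence"`
#' @param close re-close rows to sum 1 over the retained taxa (default);
#'   `FALSE` keeps the original relative abundances for sensitivity analysis
#' @return a [predictor_matrix()]
#' @export
reduce_to_top <- function(table, n_keep, statistic = c("mean", "prevalence"),
                          close = TRUE) {
  statistic <- match.arg(statistic)
  vals <- as_design(table)
  if (inherits(table, "predictor_matrix")) {
    rel <- vals  # already proportions
  } else {
    rel <- vals / rowSums(vals)
  }
  p <- ncol(rel)
  n_keep <- stopifnot_scalar_count(n_keep, "n_keep")
  if (n_keep > p) stop("n_keep exceeds the number of taxa", call. = FALSE)
  score <- switch(statistic,
                  mean = colMeans(rel),
                  prevalence = colMeans(vals > 0))
  ids <- colnames(rel)
  ord <- order(-score, ids)
  keep <- sort(ord[seq_len(n_keep)])
  coverage <- mean(rowSums(rel[, keep, drop = FALSE]))
  out <- rel[, keep, drop = FALSE]
  if (close) out <- out / rowSums(out)
  predictor_matrix(out, rownames(rel), ids[keep], coverage = coverage)
}
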