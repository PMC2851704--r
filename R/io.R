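TRIALS_HEADER <- c("review_id", "outcome_name", "trial_id", "measure",
                   "point", "ci_lower", "ci_upper", "ci_level", "n",
                   "model", "direction_of_benefit")

#' Write review outcomes to the trials CSV schema
#'
#' One row per trial per review outcome, with the fixed, ordered header
#' `review_id, outcome_name, trial_id, measure, point, ci_lower, ci_upper,
#' ci_level, n, model, direction_of_benefit`. Missing `n` is written as an
#' empty field; numbers keep full precision.
#'
#' @param reviews List of [review_outcome()] objects or a `"sim_corpus"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(reviews, path) {
  if (inherits(reviews, "sim_corpus")) reviews <- reviews$reviews
  if (inherits(reviews, "review_outcome")) reviews <- list(reviews)
  rows <- lapply(reviews, function(rv) {
    do.call(rbind, lapply(rv$trials, function(t) {
      data.frame(review_id = rv$review_id, outcome_name = rv$outcome_name,
                 trial_id = t$trial_id, measure = t$measure,
                 point = t$point, ci_lower = t$ci_lower,
                 ci_upper = t$ci_upper, ci_level = t$ci_level,
                 n = if (is.na(t$n)) NA_integer_ else t$n,
                 model = rv$model,
                 direction_of_benefit = t$direction_of_benefit,
                 stringsAsFactors = FALSE)
    }))
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(stats::setNames(rep(list(character(0)),
                                      length(TRIALS_HEADER)), TRIALS_HEADER))
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read review outcomes from a trials CSV
#'
#' Parses and validates the trials CSV schema (see [write_trials_csv()] for
#' the exact header). Rows are grouped by `(review_id, outcome_name)`;
#' validation is all-or-nothing per review: any invalid row invalidates its
#' whole review, which is excluded with a row-numbered reason, while the
#' remaining reviews load normally. Exclusions are attached as the
#' `"exclusions"` attribute (a data frame with `review_id`, `row`,
#' `reason`).
#'
#' @param path Path to a trials CSV file.
#' @return A list of [review_outcome()] objects with an `"exclusions"`
#'   attribute.
#' @export
read_trials_csv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("read_trials_csv: no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  if (!identical(names(df), TRIALS_HEADER))
    stop(sprintf("read_trials_csv: header mismatch; expected exactly: %s",
                 paste(TRIALS_HEADER, collapse = ",")), call. = FALSE)
  excl <- list()
  reviews <- list()
  if (!nrow(df)) {
    out <- list()
    attr(out, "exclusions") <- data.frame(review_id = character(),
                                          row = integer(),
                                          reason = character(),
                                          stringsAsFactors = FALSE)
    return(out)
  }
  df$.row <- seq_len(nrow(df)) + 1L  # file row numbers (header is row 1)
  key <- paste(df$review_id, df$outcome_name, sep = "\r")
  for (kk in unique(key)) {
    sub <- df[key == kk, , drop = FALSE]
    parsed <- tryCatch({
      models <- unique(sub$model)
      if (length(models) != 1 || !models %in% c("fixed", "random"))
        stop(sprintf("row %d: review must declare one model, 'fixed' or 'random'",
                     sub$.row[1]))
      trials <- lapply(seq_len(nrow(sub)), function(i) {
        r <- sub[i, ]
        tryCatch(
          trial_effect(r$trial_id, r$measure,
                       as_num(r$point, "point", r$.row),
                       as_num(r$ci_lower, "ci_lower", r$.row),
                       as_num(r$ci_upper, "ci_upper", r$.row),
                       ci_level = if (!nzchar(r$ci_level)) 0.95
                                  else as_num(r$ci_level, "ci_level", r$.row),
                       n = if (!nzchar(r$n)) NA_integer_
                           else as_num(r$n, "n", r$.row),
                       direction_of_benefit =
                         if (!nzchar(r$direction_of_benefit))
                           "less_than_null" else r$direction_of_benefit),
          error = function(e)
            stop(sprintf("row %d: %s", r$.row, conditionMessage(e)),
                 call. = FALSE))
      })
      review_outcome(sub$review_id[1], sub$outcome_name[1], trials,
                     model = models)
    }, error = identity)
    if (inherits(parsed, "error")) {
      excl[[length(excl) + 1L]] <- data.frame(
        review_id = sub$review_id[1], row = sub$.row[1],
        reason = conditionMessage(parsed), stringsAsFactors = FALSE)
    } else {
      reviews[[length(reviews) + 1L]] <- parsed
    }
  }
  attr(reviews, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(review_id = character(), row = integer(),
               reason = character(), stringsAsFactors = FALSE)
  reviews
}

as_num <- function(x, field, row) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v))
    stop(sprintf("row %d: field '%s' is not numeric ('%s')", row, field, x),
         call. = FALSE)
  v
}

#' Write the concordance reports to a directory
#'
#' Emits the machine-readable outputs of a concordance analysis: the
#' agreement table with conditional rates (`agreement.json` and
#' `agreement.csv`), per-review records (`records.csv`), the discrepancy
#' report (`discrepancy.csv`), and the scatter exports pairing trial and
#' meta-analysis estimates and p-values (`scatter_estimates.csv`,
#' `scatter_pvalues.csv`).
#'
#' @param cc A `"concordance"` object.
#' @param dir Output directory (created if missing).
#' @param threshold Weight-share threshold for the scatter strata.
#' @return The directory path, invisibly.
#' @export
write_concordance_reports <- function(cc, dir, threshold = 0.5) {
  stopifnot(inherits(cc, "concordance"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- cc$table
  agree <- list(alpha = tab$alpha, n11 = tab$n11, n10 = tab$n10,
                n01 = tab$n01, n00 = tab$n00,
                single_trial_significant = tab$single_sig,
                single_trial_nonsignificant = tab$single_nonsig,
                total = tab$total, rates = cc$rates)
  jsonlite::write_json(agree, file.path(dir, "agreement.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.csv(
    data.frame(cell = c("n11", "n10", "n01", "n00"),
               count = c(tab$n11, tab$n10, tab$n01, tab$n00)),
    file.path(dir, "agreement.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(cc$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(discrepancy_report(cc$records),
                   file.path(dir, "discrepancy.csv"), row.names = FALSE)
  strata <- stratify_by_weight(cc$records, threshold = threshold)
  utils::write.csv(strata$points$estimates,
                   file.path(dir, "scatter_estimates.csv"), row.names = FALSE)
  utils::write.csv(strata$points$pvalues,
                   file.path(dir, "scatter_pvalues.csv"), row.names = FALSE)
  invisible(dir)
}
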