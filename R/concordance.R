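#' One review outcome: a set of trials and the pooling model its authors chose
#'
#' @param review_id Opaque review label.
#' @param outcome_name Outcome description.
#' @param trials List of [trial_effect()] objects (length >= 1).
#' @param model `"fixed"` or `"random"`: the pooling model declared by the
#'   review authors. The pipeline respects this choice rather than re-deciding
#'   it.
#' @param pooled_override Optional externally supplied `"meta_pool"` object,
#'   for reviews where only the summary row is available; when present it is
#'   used in place of re-pooling the trials.
#' @return An object of class `"review_outcome"`.
#' @export
review_outcome <- function(review_id, outcome_name, trials,
                           model = c("fixed", "random"),
                           pooled_override = NULL) {
  model <- match.arg(model)
  if (inherits(trials, "trial_effect")) trials <- list(trials)
  if (!length(trials) && is.null(pooled_override))
    stop("review_outcome: needs at least one trial or a pooled_override",
         call. = FALSE)
  ok <- vapply(trials, inherits, logical(1), what = "trial_effect")
  if (!all(ok))
    stop("review_outcome: trials must be trial_effect objects", call. = FALSE)
  if (!is.null(pooled_override) && !inherits(pooled_override, "meta_pool"))
    stop("review_outcome: pooled_override must be a meta_pool object",
         call. = FALSE)
  structure(
    list(review_id = as.character(review_id),
         outcome_name = as.character(outcome_name),
         trials = trials, model = model, pooled_override = pooled_override),
    class = "review_outcome"
  )
}

#' @export
print.review_outcome <- function(x, ...) {
  cat(sprintf("<review_outcome> %s / %s: %d trial(s), %s-effect model%s\n",
              x$review_id, x$outcome_name, length(x$trials), x$model,
              if (is.null(x$pooled_override)) "" else " (pooled override)"))
  invisible(x)
}

#' Pool a review outcome under its declared model
#'
#' @param review A [review_outcome()].
#' @param model Optional override of the review's declared model.
#' @param ... Passed to [meta_pool()].
#' @return A `"meta_pool"` object (the `pooled_override`, if one was given).
#' @export
pool_review <- function(review, model = NULL, ...) {
  stopifnot(inherits(review, "review_outcome"))
  if (!is.null(review$pooled_override)) return(review$pooled_override)
  effects <- lapply(review$trials, to_analysis_scale)
  ae <- check_effect_list(effects)
  meta_pool(ae$y, ae$se, model = if (is.null(model)) review$model else model,
            scale = ae$scale, ci_level = review$trials[[1]]$ci_level, ...)
}

#' Identify the most precise trial in a review outcome
#'
#' The most precise ("largest", highest-weighted) trial is the one
#' contributing the greatest inverse-variance weight to the meta-analysis,
#' under the review's declared pooling model. Ties on weight are broken by
#' the larger sample size, then by input order.
#'
#' @param review A [review_outcome()].
#' @param model Optional override of the declared model.
#' @return A list with `index` (position in `review$trials`) and
#'   `weight_share` (that trial's weight fraction, in (0, 1\]).
#' @export
most_precise_trial <- function(review, model = NULL) {
  stopifnot(inherits(review, "review_outcome"))
  if (!length(review$trials))
    stop("most_precise_trial: review has no trial rows", call. = FALSE)
  effects <- lapply(review$trials, to_analysis_scale)
  ae <- check_effect_list(effects)
  fit <- meta_pool(ae$y, ae$se,
                   model = if (is.null(model)) review$model else model,
                   scale = ae$scale)
  fr <- fit$weights
  top <- which(fr >= max(fr) - 1e-12)
  if (length(top) > 1) {
    n <- vapply(review$trials[top], function(t) {
      if (is.na(t$n)) -Inf else as.numeric(t$n)
    }, numeric(1))
    top <- top[order(-n, seq_along(top))][1]
  }
  list(index = top[1], weight_share = fr[top[1]])
}

#' Dichotomize a p-value at a significance level
#'
#' Strict inequality: `p < alpha` is significant; the boundary `p == alpha`
#' is not.
#'
#' @param p Numeric p-values in \[0, 1\].
#' @param alpha Significance level (default 0.05).
#' @return Logical vector.
#' @export
classify_significance <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("classify_significance: p must lie in [0, 1]", call. = FALSE)
  p < alpha
}

AGREEMENT_CLASSES <- c("both_sig", "both_nonsig", "trial_sig_only",
                       "meta_sig_only", "single_trial_sig",
                       "single_trial_nonsig")

effect_direction <- function(y, direction_of_benefit) {
  if (y == 0) return("neutral")
  if ((y < 0) == (direction_of_benefit == "less_than_null")) "favors"
  else "against"
}

#' Pair the most precise trial with its meta-analysis
#'
#' Pools the review outcome under its declared model, identifies the most
#' precise trial, recomputes that trial's two-sided p-value by a z-test on
#' the analysis scale (log for ratio measures), and classifies agreement in
#' statistical significance at `alpha`. Single-trial reviews are classified
#' `single_trial_sig` / `single_trial_nonsig` (trial and meta-analysis
#' coincide by construction).
#'
#' @param review A [review_outcome()].
#' @param alpha Significance level for dichotomizing p-values.
#' @return A one-row data frame (a "concordance record") with columns
#'   `review_id`, `outcome_name`, `k`, `measure_class`, `trial_id`,
#'   `trial_y`, `trial_se`, `trial_p`, `meta_y`, `meta_se`, `meta_p`,
#'   `trial_estimate`, `meta_estimate` (natural scale), `weight_share`,
#'   `i2`, `trial_sig`, `meta_sig`, `agreement_class`, `trial_direction`,
#'   `meta_direction`.
#' @export
build_concordance <- function(review, alpha = 0.05) {
  stopifnot(inherits(review, "review_outcome"))
  pooled <- tryCatch(pool_review(review), error = function(e) {
    stop(sprintf("review %s: %s", review$review_id, conditionMessage(e)),
         call. = FALSE)
  })
  mp <- most_precise_trial(review)
  trial <- review$trials[[mp$index]]
  ae <- to_analysis_scale(trial)
  trial_p <- pvalue_limit(ae$y, ae$se)
  k <- length(review$trials)
  trial_sig <- classify_significance(trial_p, alpha)
  meta_sig <- classify_significance(pooled$p, alpha)
  cls <- if (k == 1) {
    if (trial_sig) "single_trial_sig" else "single_trial_nonsig"
  } else if (trial_sig && meta_sig) "both_sig"
  else if (trial_sig) "trial_sig_only"
  else if (meta_sig) "meta_sig_only"
  else "both_nonsig"
  back <- if (ae$scale == "log") exp else identity
  data.frame(
    review_id = review$review_id,
    outcome_name = review$outcome_name,
    k = k,
    measure_class = if (ae$scale == "log") "ratio" else "difference",
    trial_id = trial$trial_id,
    trial_y = ae$y, trial_se = ae$se, trial_p = trial_p,
    meta_y = pooled$y_pooled, meta_se = pooled$se_pooled, meta_p = pooled$p,
    trial_estimate = back(ae$y), meta_estimate = pooled$estimate,
    weight_share = mp$weight_share,
    i2 = pooled$het$i2,
    trial_sig = trial_sig, meta_sig = meta_sig,
    agreement_class = cls,
    trial_direction = effect_direction(ae$y, trial$direction_of_benefit),
    meta_direction = effect_direction(pooled$y_pooled,
                                      trial$direction_of_benefit),
    stringsAsFactors = FALSE
  )
}

#' Run the concordance pipeline over a corpus of review outcomes
#'
#' Builds one concordance record per evaluable review outcome (reviews whose
#' pooling fails are excluded with a logged reason), then tabulates agreement
#' in statistical significance between each review's most precise trial and
#' its full meta-analysis.
#'
#' @param reviews List of [review_outcome()] objects (e.g. from
#'   [read_trials_csv()] or [simulate_corpus()]).
#' @param alpha Significance level.
#' @return An object of class `"concordance"`: a list with `records` (data
#'   frame of per-review records, see [build_concordance()]), `table` (an
#'   [agreement_table()]), `rates` ([conditional_rates()]), `alpha`, and
#'   `exclusions` (data frame of review_id/reason for non-evaluable reviews).
#' @examples
#' corpus <- synthetic_concordance_corpus()
#' cc <- concordance(corpus)
#' cc
#' @export
concordance <- function(reviews, alpha = 0.05) {
  if (inherits(reviews, "review_outcome")) reviews <- list(reviews)
  if (inherits(reviews, "sim_corpus")) reviews <- reviews$reviews
  rec_list <- list()
  excl <- list()
  for (rv in reviews) {
    r <- tryCatch(build_concordance(rv, alpha = alpha), error = identity)
    if (inherits(r, "error")) {
      excl[[length(excl) + 1L]] <- data.frame(
        review_id = rv$review_id, reason = conditionMessage(r),
        stringsAsFactors = FALSE)
    } else {
      rec_list[[length(rec_list) + 1L]] <- r
    }
  }
  records <- if (length(rec_list)) do.call(rbind, rec_list) else
    empty_records()
  tab <- agreement_table(records, alpha = alpha)
  structure(
    list(records = records, table = tab, rates = conditional_rates(tab),
         alpha = alpha,
         exclusions = if (length(excl)) do.call(rbind, excl) else
           data.frame(review_id = character(), reason = character(),
                      stringsAsFactors = FALSE)),
    class = "concordance"
  )
}

empty_records <- function() {
  data.frame(review_id = character(), outcome_name = character(),
             k = integer(), measure_class = character(),
             trial_id = character(), trial_y = numeric(),
             trial_se = numeric(), trial_p = numeric(), meta_y = numeric(),
             meta_se = numeric(), meta_p = numeric(),
             trial_estimate = numeric(), meta_estimate = numeric(),
             weight_share = numeric(), i2 = numeric(), trial_sig = logical(),
             meta_sig = logical(), agreement_class = character(),
             trial_direction = character(), meta_direction = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("Concordance analysis of %d review outcomes (alpha = %g)\n\n",
              nrow(x$records), x$alpha))
  print(x$table)
  r <- x$rates
  cat(sprintf("\nP(meta sig | trial sig)    = %s\n",
              format_rate(r$p_meta_sig_given_trial_sig)))
  cat(sprintf("P(meta sig | trial nonsig) = %s\n",
              format_rate(r$p_meta_sig_given_trial_nonsig)))
  cat(sprintf("Overall agreement          = %s\n",
              format_rate(r$overall_agreement)))
  if (nrow(x$exclusions))
    cat(sprintf("\n%d review(s) excluded (not poolable)\n", nrow(x$exclusions)))
  invisible(x)
}

format_rate <- function(r) {
  if (is.na(r)) "undefined (zero denominator)" else sprintf("%.1f%%", 100 * r)
}

#' @export
summary.concordance <- function(object, ...) {
  strata <- stratify_by_weight(object$records)
  rho <- lapply(c(ratio = "ratio", difference = "difference",
                  standardized = "standardized"), function(cl) {
    tryCatch(estimate_rank_correlation(object$records, cl),
             error = function(e) NA_real_)
  })
  structure(list(cc = object, strata = strata, rho = rho),
            class = "summary.concordance")
}

#' @export
print.summary.concordance <- function(x, ...) {
  print(x$cc)
  cat("\nRank correlation (trial vs meta estimates):\n")
  for (nm in names(x$rho))
    cat(sprintf("  %-13s %s\n", nm,
                if (is.na(x$rho[[nm]])) "n/a (fewer than 3 records)"
                else sprintf("%.3f", x$rho[[nm]])))
  cat("\nStrata by most-precise-trial weight share:\n")
  print(x$strata$summary, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Two-by-two agreement table on statistical significance
#'
#' Cross-classifies concordance records by whether the most precise trial
#' and the meta-analysis were statistically significant. Single-trial
#' reviews land on the diagonal by construction and are tracked as
#' sub-counts.
#'
#' @param records Data frame of concordance records (or a `"concordance"`
#'   object).
#' @param alpha The significance level the records were classified at
#'   (recorded in the table).
#' @return An object of class `"agreement_table"`: counts `n11` (both
#'   significant), `n10` (trial only), `n01` (meta only), `n00` (neither),
#'   `single_sig` and `single_nonsig` sub-counts, `total`, `alpha`.
#' @export
agreement_table <- function(records, alpha = 0.05) {
  records <- as_records(records)
  cls <- records$agreement_class
  structure(
    list(n11 = sum(cls %in% c("both_sig", "single_trial_sig")),
         n10 = sum(cls == "trial_sig_only"),
         n01 = sum(cls == "meta_sig_only"),
         n00 = sum(cls %in% c("both_nonsig", "single_trial_nonsig")),
         single_sig = sum(cls == "single_trial_sig"),
         single_nonsig = sum(cls == "single_trial_nonsig"),
         total = length(cls), alpha = alpha),
    class = "agreement_table"
  )
}

as_records <- function(records) {
  if (inherits(records, "concordance")) records <- records$records
  stopifnot(is.data.frame(records))
  records
}

#' @export
print.agreement_table <- function(x, ...) {
  cat(sprintf("Agreement on statistical significance (alpha = %g, n = %d)\n",
              x$alpha, x$total))
  m <- matrix(c(x$n11, x$n10, x$n01, x$n00), 2, 2, byrow = TRUE,
              dimnames = list(c("trial sig", "trial nonsig"),
                              c("meta sig", "meta nonsig")))
  print(m)
  cat(sprintf("(diagonal includes %d significant and %d non-significant single-trial reviews)\n",
              x$single_sig, x$single_nonsig))
  invisible(x)
}

#' Conditional significance rates from an agreement table
#'
#' @param table An [agreement_table()].
#' @return A list with `p_meta_sig_given_trial_sig` = n11/(n11+n10),
#'   `p_meta_sig_given_trial_nonsig` = n01/(n01+n00), and
#'   `overall_agreement` = (n11+n00)/total. A zero denominator yields
#'   `NA_real_` (an explicit undefined marker), never an error.
#' @export
conditional_rates <- function(table) {
  stopifnot(inherits(table, "agreement_table"))
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  list(
    p_meta_sig_given_trial_sig = safe_div(table$n11, table$n11 + table$n10),
    p_meta_sig_given_trial_nonsig = safe_div(table$n01, table$n01 + table$n00),
    overall_agreement = safe_div(table$n11 + table$n00, table$total)
  )
}

#' Rank correlation between trial and meta-analysis estimates
#'
#' Spearman correlation (Pearson on mid-ranks) of the most precise trial's
#' estimate against the pooled estimate, within one measure class. Ratio and
#' difference records live on different scales, so they are never silently
#' mixed: the `"standardized"` class combines them after dividing each
#' analysis-scale estimate by its standard error.
#'
#' @param records Concordance records (or a `"concordance"` object).
#' @param measure_class `"ratio"`, `"difference"`, or `"standardized"`.
#' @return Spearman's rho.
#' @export
estimate_rank_correlation <- function(records,
                                      measure_class = c("ratio", "difference",
                                                        "standardized")) {
  measure_class <- match.arg(measure_class)
  records <- as_records(records)
  if (measure_class == "standardized") {
    if (any(records$trial_se == 0) || any(records$meta_se == 0))
      stop("standardized correlation undefined with zero standard errors",
           call. = FALSE)
    x <- records$trial_y / records$trial_se
    y <- records$meta_y / records$meta_se
  } else {
    keep <- records$measure_class == measure_class
    x <- records$trial_y[keep]
    y <- records$meta_y[keep]
  }
  if (length(x) < 3)
    stop(sprintf("need at least 3 records in class '%s' (have %d)",
                 measure_class, length(x)), call. = FALSE)
  stats::cor(x, y, method = "spearman")
}

#' Relationship between a trial's CI and the pooled result
#'
#' @param trial A [trial_effect()].
#' @param pooled A `"meta_pool"` object on the same scale (log-scale pooled
#'   fit for a ratio-measure trial, identity for a difference).
#' @return A list of flags: `contains_pooled_estimate` (the pooled point
#'   estimate lies inside the trial's CI) and `intervals_overlap` (the two
#'   CIs intersect). Comparison is on the natural scale; the log map is
#'   monotone so containment and overlap are scale-invariant.
#' @export
ci_relationship <- function(trial, pooled) {
  stopifnot(inherits(trial, "trial_effect"), inherits(pooled, "meta_pool"))
  trial_scale <- if (is_ratio_measure(trial$measure)) "log" else "identity"
  if (trial_scale != pooled$scale)
    stop("ci_relationship: trial and pooled result are on different scales",
         call. = FALSE)
  list(
    contains_pooled_estimate =
      pooled$estimate >= trial$ci_lower && pooled$estimate <= trial$ci_upper,
    intervals_overlap =
      max(trial$ci_lower, pooled$ci_lower) <=
      min(trial$ci_upper, pooled$ci_upper)
  )
}

#' Report the reviews where the trial was significant but the pooled result was not
#'
#' One row per `trial_sig_only` record, sorted by review id, with the trial
#' count, both p-values, the most precise trial's weight share, both effect
#' estimates (natural scale) and the I-squared heterogeneity of the
#' meta-analysis.
#'
#' @param records Concordance records (or a `"concordance"` object).
#' @return A data frame (possibly empty).
#' @export
discrepancy_report <- function(records) {
  records <- as_records(records)
  d <- records[records$agreement_class == "trial_sig_only",
               c("review_id", "outcome_name", "k", "meta_p", "trial_p",
                 "weight_share", "meta_estimate", "trial_estimate", "i2")]
  d <- d[order(d$review_id), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Stratify concordance records by the most precise trial's weight share
#'
#' Splits records at a weight-share threshold (share > threshold versus
#' share <= threshold) and summarises each stratum: record count, rate of
#' agreement in statistical significance, and the rank correlation of
#' se-standardized trial versus pooled estimates. Also returns the paired
#' point sets used for estimate-vs-estimate and p-vs-p scatter exports.
#'
#' @param records Concordance records (or a `"concordance"` object).
#' @param threshold Weight-share cut point (default 0.5).
#' @return A list with `summary` (one row per stratum) and `points` (list of
#'   data frames `estimates` and `pvalues`, each carrying a `stratum`
#'   column).
#' @export
stratify_by_weight <- function(records, threshold = 0.5) {
  records <- as_records(records)
  stratum <- ifelse(records$weight_share > threshold,
                    sprintf("share > %g", threshold),
                    sprintf("share <= %g", threshold))
  levs <- c(sprintf("share > %g", threshold), sprintf("share <= %g", threshold))
  summ <- do.call(rbind, lapply(levs, function(s) {
    r <- records[stratum == s, , drop = FALSE]
    rho <- NA_real_
    if (nrow(r) >= 3 && all(r$trial_se > 0) && all(r$meta_se > 0)) {
      sx <- r$trial_y / r$trial_se
      sy <- r$meta_y / r$meta_se
      # rank correlation is undefined for a constant margin
      if (stats::var(sx) > 0 && stats::var(sy) > 0)
        rho <- stats::cor(sx, sy, method = "spearman")
    }
    data.frame(stratum = s, n = nrow(r),
               agreement_rate = if (nrow(r)) mean(r$trial_sig == r$meta_sig)
                                else NA_real_,
               rank_correlation = rho, stringsAsFactors = FALSE)
  }))
  list(
    summary = summ,
    points = list(
      estimates = data.frame(review_id = records$review_id,
                             trial_y = records$trial_y,
                             meta_y = records$meta_y,
                             weight_share = records$weight_share,
                             measure_class = records$measure_class,
                             stratum = stratum, stringsAsFactors = FALSE),
      pvalues = data.frame(review_id = records$review_id,
                           trial_p = records$trial_p,
                           meta_p = records$meta_p,
                           stratum = stratum, stringsAsFactors = FALSE)
    )
  )
}
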