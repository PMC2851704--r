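#' @keywords internal
#' @importFrom stats qnorm pnorm
#' @importFrom graphics abline axis points segments
"_PACKAGE"

RATIO_MEASURES <- c("RR", "OR", "HR")
DIFF_MEASURES <- c("MD", "WMD")
MEASURES <- c(RATIO_MEASURES, DIFF_MEASURES)
DIRECTIONS <- c("less_than_null", "greater_than_null")

#' Is a measure a ratio measure?
#'
#' Relative risks, odds ratios and hazard ratios are all analysed on the log
#' scale; (weighted) mean differences on the identity scale.
#'
#' @param measure Character vector of measure codes (`"RR"`, `"OR"`, `"HR"`,
#'   `"MD"`, `"WMD"`).
#' @return Logical vector.
#' @export
is_ratio_measure <- function(measure) {
  measure %in% RATIO_MEASURES
}

#' One trial's reported effect estimate
#'
#' Constructs and validates a single trial's effect estimate as reported in a
#' review: a point estimate and confidence interval on the natural scale,
#' together with the measure type, the total number randomized, and which side
#' of the null favors the experimental treatment.
#'
#' @param trial_id Opaque trial label.
#' @param measure One of `"RR"`, `"OR"`, `"HR"` (ratio measures, analysed on
#'   the log scale) or `"MD"`, `"WMD"` (differences, identity scale).
#' @param point Point estimate on the natural scale.
#' @param ci_lower,ci_upper Confidence-interval bounds on the natural scale;
#'   must bracket `point`. Ratio measures require strictly positive values.
#' @param ci_level Confidence level as a fraction in (0, 1); default 0.95.
#' @param n Total randomized participants (optional positive integer, `NA` if
#'   unknown).
#' @param direction_of_benefit `"less_than_null"` or `"greater_than_null"`:
#'   which side of the null favors the experimental arm. Metadata only; it
#'   never enters a p-value.
#' @return An object of class `"trial_effect"`.
#' @examples
#' trial_effect("t1", "RR", 0.5, 0.25, 1.0)
#' @export
trial_effect <- function(trial_id, measure, point, ci_lower, ci_upper,
                         ci_level = 0.95, n = NA_integer_,
                         direction_of_benefit = "less_than_null") {
  measure <- match.arg(measure, MEASURES)
  direction_of_benefit <- match.arg(direction_of_benefit, DIRECTIONS)
  point <- as.numeric(point)
  ci_lower <- as.numeric(ci_lower)
  ci_upper <- as.numeric(ci_upper)
  ci_level <- as.numeric(ci_level)
  if (!is.finite(point) || !is.finite(ci_lower) || !is.finite(ci_upper))
    stop("trial_effect: point and CI bounds must be finite", call. = FALSE)
  if (ci_upper < ci_lower)
    stop("trial_effect: ci_upper < ci_lower", call. = FALSE)
  if (point < ci_lower || point > ci_upper)
    stop("trial_effect: point estimate outside its confidence interval",
         call. = FALSE)
  if (!is.finite(ci_level) || ci_level <= 0 || ci_level >= 1)
    stop("trial_effect: ci_level must lie strictly in (0, 1)", call. = FALSE)
  if (is_ratio_measure(measure) && ci_lower <= 0)
    stop("trial_effect: ratio measures require strictly positive estimates",
         call. = FALSE)
  if (!is.na(n)) {
    n <- as.integer(n)
    if (is.na(n) || n <= 0)
      stop("trial_effect: n must be a positive integer or NA", call. = FALSE)
  }
  structure(
    list(trial_id = as.character(trial_id), measure = measure, point = point,
         ci_lower = ci_lower, ci_upper = ci_upper, ci_level = ci_level,
         n = n, direction_of_benefit = direction_of_benefit),
    class = "trial_effect"
  )
}

#' @export
print.trial_effect <- function(x, ...) {
  cat(sprintf("<trial_effect> %s: %s %.4g [%.4g, %.4g] (%.0f%% CI)%s\n",
              x$trial_id, x$measure, x$point, x$ci_lower, x$ci_upper,
              100 * x$ci_level,
              if (is.na(x$n)) "" else sprintf(", n = %d", x$n)))
  invisible(x)
}

#' Map a reported effect onto its analysis scale
#'
#' Ratio measures (RR/OR/HR) are mapped by the natural logarithm; differences
#' are left on the identity scale. The standard error is recovered from the
#' confidence interval assuming symmetry on the analysis scale:
#' `se = (g(upper) - g(lower)) / (2 * z)` with `z` the exact standard-normal
#' quantile for the interval's level (1.959964... at 95%, not the rounded
#' 1.96). A degenerate interval (upper = lower = point) yields `se = 0`.
#'
#' @param trial A [trial_effect()].
#' @param z_quantile Optional override for the normal quantile, e.g. `1.96`
#'   to match software that used the rounded value when the source interval
#'   was computed.
#' @return An object of class `"analysis_effect"`: a list with `y` (estimate
#'   on the analysis scale), `se`, `scale` (`"log"` or `"identity"`) and
#'   `null_value` (always 0 on the analysis scale).
#' @examples
#' to_analysis_scale(trial_effect("t1", "RR", 0.5, 0.25, 1.0))
#' @export
to_analysis_scale <- function(trial, z_quantile = NULL) {
  stopifnot(inherits(trial, "trial_effect"))
  g <- if (is_ratio_measure(trial$measure)) log else identity
  z <- if (is.null(z_quantile)) ci_quantile(trial$ci_level) else z_quantile
  y <- g(trial$point)
  se <- (g(trial$ci_upper) - g(trial$ci_lower)) / (2 * z)
  structure(
    list(y = y, se = se,
         scale = if (is_ratio_measure(trial$measure)) "log" else "identity",
         null_value = 0),
    class = "analysis_effect"
  )
}

# exact two-sided normal quantile for a CI level in (0,1)
ci_quantile <- function(level) {
  stats::qnorm(1 - (1 - level) / 2)
}

#' Two-sided z-test p-value for an analysis-scale effect
#'
#' `p = 2 * (1 - Phi(|y - null| / se))`. A zero standard error is only
#' admissible when the estimate sits exactly at the null (then `p = 1`);
#' otherwise the p-value is undefined and an error is raised.
#'
#' @param y Estimate on the analysis scale, or an `"analysis_effect"` object
#'   (in which case `se` and `null` are taken from it).
#' @param se Standard error on the analysis scale, `>= 0`.
#' @param null Null value on the analysis scale (default 0: a ratio of 1 or a
#'   difference of 0).
#' @return Two-sided p-value in \[0, 1\].
#' @examples
#' z_pvalue(0, 1)                     # 1
#' z_pvalue(to_analysis_scale(trial_effect("t", "RR", 0.5, 0.25, 1)))
#' @export
z_pvalue <- function(y, se = NULL, null = 0) {
  if (inherits(y, "analysis_effect")) {
    se <- y$se
    null <- y$null_value
    y <- y$y
  }
  if (!is.numeric(y) || !is.numeric(se) || length(y) != length(se))
    stop("z_pvalue: y and se must be numeric vectors of equal length",
         call. = FALSE)
  if (any(se < 0)) stop("z_pvalue: se must be nonnegative", call. = FALSE)
  if (any(se == 0 & y != null))
    stop("z_pvalue: p undefined for se = 0 with estimate off the null",
         call. = FALSE)
  p <- ifelse(se == 0, 1, 2 * stats::pnorm(-abs(y - null) / se))
  p
}

# p-value with the degenerate-se continuity limit (used inside pooling so a
# single zero-variance trial flows through rather than erroring)
pvalue_limit <- function(y, se, null = 0) {
  if (se == 0) return(if (y == null) 1 else 0)
  2 * stats::pnorm(-abs(y - null) / se)
}
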