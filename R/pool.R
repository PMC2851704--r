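#' Inverse-variance pooling of trial effects
#'
#' Fits a fixed-effect or DerSimonian--Laird random-effects meta-analysis to
#' analysis-scale estimates `y` with standard errors `se`.
#'
#' Fixed-effect weights are `w_i = 1 / se_i^2`; the pooled estimate is the
#' weighted mean with `se_pooled = (sum w_i)^(-1/2)`. Heterogeneity is
#' summarised by Cochran's `Q = sum w_i (y_i - y_F)^2` on `df = k - 1`
#' degrees of freedom, the method-of-moments between-trial variance
#' `tau2 = max(0, (Q - df) / C)` with `C = sum(w) - sum(w^2)/sum(w)`, and
#' `I2 = max(0, (Q - df)/Q) * 100` (defined as 0 when `Q = 0` or `k = 1`).
#' The random-effects fit re-weights by `1 / (se_i^2 + tau2)`; when
#' `Q <= df` it coincides with the fixed-effect fit. Confidence limits and
#' the two-sided p-value use the normal approximation on the pooled standard
#' error (the convention of the standard review software; no small-sample
#' adjustment). A single trial (`k = 1`) is returned unchanged, with
#' `Q = df = tau2 = I2 = 0`.
#'
#' @param y Numeric vector of analysis-scale estimates (log ratios or raw
#'   differences).
#' @param se Numeric vector of standard errors; strictly positive when
#'   `k > 1` (a zero se would carry infinite weight), `>= 0` when `k = 1`.
#' @param model `"fixed"` or `"random"`.
#' @param scale `"identity"` or `"log"`; governs the back-transform of the
#'   pooled estimate and CI onto the natural scale.
#' @param ci_level Confidence level in (0, 1).
#' @param z_quantile Optional override of the normal quantile used for the CI
#'   (e.g. `1.96` for compatibility with rounded published intervals).
#' @return An object of class `"meta_pool"` with components `y_pooled`,
#'   `se_pooled`, `estimate`/`ci_lower`/`ci_upper` (natural scale), `p`,
#'   `weights` (fractions summing to 1), `k`, `model`, `scale`, `het`
#'   (list with `Q`, `df`, `tau2`, `C`, `i2`), and the inputs `y`, `se`.
#' @examples
#' fit <- meta_pool(c(0, 0, 0.6), c(1, 1, 0.5))
#' coef(fit)
#' weights(fit)
#' summary(meta_pool(c(0, 2), c(1, 1), model = "random"))
#' @seealso [pool_review()] to pool a [review_outcome()] directly.
#' @export
meta_pool <- function(y, se, model = c("fixed", "random"),
                      scale = c("identity", "log"), ci_level = 0.95,
                      z_quantile = NULL) {
  model <- match.arg(model)
  scale <- match.arg(scale)
  if (!is.numeric(y) || !is.numeric(se) || length(y) != length(se))
    stop("meta_pool: y and se must be numeric vectors of equal length",
         call. = FALSE)
  k <- length(y)
  if (k < 1) stop("meta_pool: no trials to pool", call. = FALSE)
  if (any(!is.finite(y)) || any(!is.finite(se)))
    stop("meta_pool: estimates and standard errors must be finite",
         call. = FALSE)
  if (any(se < 0)) stop("meta_pool: negative standard error", call. = FALSE)
  if (k > 1 && any(se == 0))
    stop("meta_pool: se = 0 carries infinite weight; not poolable with k > 1",
         call. = FALSE)
  if (!is.finite(ci_level) || ci_level <= 0 || ci_level >= 1)
    stop("meta_pool: ci_level must lie strictly in (0, 1)", call. = FALSE)
  zq <- if (is.null(z_quantile)) ci_quantile(ci_level) else z_quantile

  if (k == 1) {
    # identity: the pooled result is the trial itself, bit for bit
    y_pooled <- y
    se_pooled <- se
    het <- list(Q = 0, df = 0, tau2 = 0, C = 0, i2 = 0)
    wfrac <- 1
  } else {
    w <- 1 / se^2
    sw <- sum(w)
    y_fixed <- sum(w * y) / sw
    Q <- sum(w * (y - y_fixed)^2)
    df <- k - 1
    C <- sw - sum(w^2) / sw
    tau2 <- max(0, (Q - df) / C)
    i2 <- if (Q <= 0) 0 else max(0, (Q - df) / Q) * 100
    het <- list(Q = Q, df = df, tau2 = tau2, C = C, i2 = i2)
    if (model == "fixed") {
      y_pooled <- y_fixed
      se_pooled <- 1 / sqrt(sw)
      wfrac <- w / sw
    } else {
      ws <- 1 / (se^2 + tau2)
      y_pooled <- sum(ws * y) / sum(ws)
      se_pooled <- 1 / sqrt(sum(ws))
      wfrac <- ws / sum(ws)
    }
  }

  lo <- y_pooled - zq * se_pooled
  hi <- y_pooled + zq * se_pooled
  back <- if (scale == "log") exp else identity
  structure(
    list(k = k, model = model, scale = scale, ci_level = ci_level,
         y = y, se = se,
         y_pooled = y_pooled, se_pooled = se_pooled,
         estimate = back(y_pooled), ci_lower = back(lo), ci_upper = back(hi),
         p = pvalue_limit(y_pooled, se_pooled),
         weights = wfrac, het = het),
    class = "meta_pool"
  )
}

#' Fixed-effect pooling of analysis-scale effects
#'
#' Convenience wrapper around [meta_pool()] taking a list of
#' `"analysis_effect"` objects (as produced by [to_analysis_scale()]); all
#' must share one analysis scale.
#'
#' @param effects List of `"analysis_effect"` objects.
#' @param ... Passed on to [meta_pool()] (`ci_level`, `z_quantile`).
#' @return A `"meta_pool"` object.
#' @export
pool_fixed <- function(effects, ...) {
  ae <- check_effect_list(effects)
  meta_pool(ae$y, ae$se, model = "fixed", scale = ae$scale, ...)
}

#' DerSimonian--Laird random-effects pooling of analysis-scale effects
#'
#' @inheritParams pool_fixed
#' @return A `"meta_pool"` object.
#' @export
pool_random_dl <- function(effects, ...) {
  ae <- check_effect_list(effects)
  meta_pool(ae$y, ae$se, model = "random", scale = ae$scale, ...)
}

check_effect_list <- function(effects) {
  if (inherits(effects, "analysis_effect")) effects <- list(effects)
  if (!length(effects)) stop("no effects to pool", call. = FALSE)
  ok <- vapply(effects, inherits, logical(1), what = "analysis_effect")
  if (!all(ok)) stop("expected a list of analysis_effect objects",
                     call. = FALSE)
  scale <- unique(vapply(effects, `[[`, character(1), "scale"))
  if (length(scale) > 1)
    stop("cannot pool effects on mixed analysis scales (log and identity)",
         call. = FALSE)
  list(y = vapply(effects, `[[`, numeric(1), "y"),
       se = vapply(effects, `[[`, numeric(1), "se"),
       scale = scale)
}

#' Per-trial inverse-variance weight fractions
#'
#' Weight fractions `w_i / sum(w)` under the fixed-effect model
#' (`w_i = 1/se_i^2`) or the DerSimonian--Laird random-effects model
#' (`w_i = 1/(se_i^2 + tau2)`); they sum to 1.
#'
#' @param effects List of `"analysis_effect"` objects, or a numeric vector of
#'   standard errors.
#' @param model `"fixed"` or `"random"`.
#' @return Numeric vector of fractions summing to 1.
#' @examples
#' weight_fractions(c(1, 0.5, 2))   # c(1, 4, 0.25) / 5.25
#' @export
weight_fractions <- function(effects, model = c("fixed", "random")) {
  model <- match.arg(model)
  if (is.numeric(effects)) {
    k <- length(effects)
    fit <- meta_pool(rep(0, k), effects, model = model)
  } else {
    ae <- check_effect_list(effects)
    fit <- meta_pool(ae$y, ae$se, model = model, scale = ae$scale)
  }
  fit$weights
}

#' @export
print.meta_pool <- function(x, digits = 4, ...) {
  cat(sprintf("%s%s inverse-variance meta-analysis, k = %d\n",
              if (x$model == "fixed") "Fixed-effect" else "Random-effects",
              if (x$model == "random") " (DerSimonian-Laird)" else "", x$k))
  cat(sprintf("  %s: %s [%s, %s] (%.0f%% CI), p = %s\n",
              if (x$scale == "log") "pooled ratio" else "pooled difference",
              format(x$estimate, digits = digits),
              format(x$ci_lower, digits = digits),
              format(x$ci_upper, digits = digits),
              100 * x$ci_level, format.pval(x$p, digits = digits)))
  cat(sprintf("  Q = %s on %d df, tau^2 = %s, I^2 = %s%%\n",
              format(x$het$Q, digits = digits), x$het$df,
              format(x$het$tau2, digits = digits),
              format(x$het$i2, digits = 3)))
  invisible(x)
}

#' @export
summary.meta_pool <- function(object, ...) {
  structure(list(fit = object), class = "summary.meta_pool")
}

#' @export
print.summary.meta_pool <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  tab <- data.frame(y = f$y, se = f$se, weight = f$weights)
  cat("\nPer-trial analysis-scale estimates and weight fractions:\n")
  print(tab, digits = digits)
  invisible(x)
}

#' @export
coef.meta_pool <- function(object, ...) {
  c(y_pooled = object$y_pooled)
}

#' @export
confint.meta_pool <- function(object, parm, level = NULL, ...) {
  # natural-scale confidence limits; `level` other than the fitted one is
  # recomputed from the pooled SE
  zq <- if (is.null(level)) ci_quantile(object$ci_level) else ci_quantile(level)
  back <- if (object$scale == "log") exp else identity
  c(lower = back(object$y_pooled - zq * object$se_pooled),
    upper = back(object$y_pooled + zq * object$se_pooled))
}

#' @importFrom stats weights
#' @export
weights.meta_pool <- function(object, ...) {
  object$weights
}

#' @export
residuals.meta_pool <- function(object, ...) {
  object$y - object$y_pooled
}

#' Forest-style plot of a pooled fit
#'
#' Base-graphics display of the per-trial estimates with their weights and
#' the pooled estimate, on the analysis scale.
#'
#' @param x A `"meta_pool"` object.
#' @param ... Further arguments passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.meta_pool <- function(x, ...) {
  zq <- ci_quantile(x$ci_level)
  k <- x$k
  ylim <- c(0.5, k + 1.5)
  lo <- x$y - zq * x$se
  hi <- x$y + zq * x$se
  xlim <- range(lo, hi, x$y_pooled)
  plot(NA, xlim = xlim, ylim = ylim, yaxt = "n",
       xlab = sprintf("estimate (%s scale)", x$scale), ylab = "", ...)
  segments(lo, k:1, hi, k:1)
  points(x$y, k:1, pch = 15, cex = 0.6 + 2 * sqrt(x$weights))
  points(x$y_pooled, 0.6, pch = 18, cex = 1.6)
  abline(v = 0, lty = 3)
  axis(2, at = c(k:1, 0.6), labels = c(paste0("trial ", seq_len(k)), "pooled"),
       las = 1, cex.axis = 0.8)
  invisible(x)
}
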