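test_that("fixed-effect pooling matches hand-computed inverse-variance arithmetic", {
  # single trial: identity, bit for bit
  fit <- meta_pool(0.37, 0.21)
  expect_identical(fit$y_pooled, 0.37)
  expect_identical(fit$se_pooled, 0.21)
  expect_identical(fit$weights, 1)
  expect_identical(fit$het$Q, 0)
  expect_identical(fit$het$i2, 0)

  # equal precision: plain average
  fit <- meta_pool(c(0.2, 0.6), c(0.5, 0.5))
  expect_equal(fit$y_pooled, 0.4, tolerance = 1e-14)

  # weights (1, 1, 4)/6, pooled = (0 + 0 + 4*0.6)/6 = 0.4
  fit <- meta_pool(c(0, 0, 0.6), c(1, 1, 0.5))
  expect_equal(fit$weights, c(1, 1, 4) / 6, tolerance = 1e-14)
  expect_equal(fit$y_pooled, 0.4, tolerance = 1e-14)
  expect_equal(fit$se_pooled, 1 / sqrt(6), tolerance = 1e-14)
})

test_that("DerSimonian-Laird pooling matches the hand computation", {
  # y = (0, 2), se = (1, 1): Q = 2, df = 1, C = 1, tau2 = 1,
  # w* = (1/2, 1/2), pooled = 1, se = 1
  fit <- meta_pool(c(0, 2), c(1, 1), model = "random")
  expect_equal(fit$het$Q, 2, tolerance = 1e-14)
  expect_equal(fit$het$C, 1, tolerance = 1e-14)
  expect_equal(fit$het$tau2, 1, tolerance = 1e-14)
  expect_equal(fit$weights, c(0.5, 0.5), tolerance = 1e-14)
  expect_equal(fit$y_pooled, 1, tolerance = 1e-14)
  expect_equal(fit$se_pooled, 1, tolerance = 1e-14)

  # identical trials: tau2 = 0, random = fixed
  fe <- meta_pool(c(0.3, 0.3, 0.3), c(0.2, 0.2, 0.2))
  re <- meta_pool(c(0.3, 0.3, 0.3), c(0.2, 0.2, 0.2), model = "random")
  expect_identical(re$het$tau2, 0)
  expect_equal(re$y_pooled, fe$y_pooled, tolerance = 1e-14)
  expect_equal(re$se_pooled, fe$se_pooled, tolerance = 1e-14)
})

test_that("pooling agrees with metafor as an independent implementation", {
  cases <- random_instances(25, seed = 402)
  for (cs in cases) {
    if (length(cs$y) < 2) next
    fe <- meta_pool(cs$y, cs$se)
    m_fe <- metafor::rma(yi = cs$y, sei = cs$se, method = "FE")
    expect_equal(fe$y_pooled, unname(as.numeric(m_fe$beta)), tolerance = 1e-8)
    expect_equal(fe$se_pooled, unname(m_fe$se), tolerance = 1e-8)
    expect_equal(fe$p, unname(m_fe$pval), tolerance = 1e-8)
    expect_equal(fe$het$Q, unname(m_fe$QE), tolerance = 1e-8)

    re <- meta_pool(cs$y, cs$se, model = "random")
    m_re <- metafor::rma(yi = cs$y, sei = cs$se, method = "DL")
    expect_equal(re$het$tau2, unname(m_re$tau2), tolerance = 1e-8)
    expect_equal(re$y_pooled, unname(as.numeric(m_re$beta)), tolerance = 1e-8)
    expect_equal(re$se_pooled, unname(m_re$se), tolerance = 1e-8)
    expect_equal(re$het$i2, unname(m_re$I2), tolerance = 1e-6)
  }
})

test_that("weight fractions follow inverse-variance arithmetic and sum to one", {
  expect_equal(weight_fractions(c(1, 0.5, 2)), c(1, 4, 0.25) / 5.25,
               tolerance = 1e-14)
  expect_equal(weight_fractions(rep(0.3, 7)), rep(1 / 7, 7),
               tolerance = 1e-14)
  expect_identical(weight_fractions(0.4), 1)
  for (cs in random_instances(200, seed = 99)) {
    expect_equal(sum(weight_fractions(cs$se)), 1, tolerance = 1e-12)
    if (length(cs$se) > 1) {
      re <- meta_pool(cs$y, cs$se, model = "random")
      expect_equal(sum(re$weights), 1, tolerance = 1e-12)
    }
  }
})

test_that("pooling invariants hold on random instances", {
  for (cs in random_instances(300, seed = 17)) {
    fe <- meta_pool(cs$y, cs$se)
    re <- meta_pool(cs$y, cs$se, model = "random")
    # convexity of the weighted mean
    expect_gte(fe$y_pooled, min(cs$y) - 1e-12)
    expect_lte(fe$y_pooled, max(cs$y) + 1e-12)
    # heterogeneity conventions
    expect_gte(re$het$tau2, 0)
    if (fe$het$Q <= fe$het$df) expect_identical(re$het$tau2, 0)
    expect_gte(fe$het$i2, 0)
    expect_lte(fe$het$i2, 100)
    # extra between-trial variance can only widen the pooled interval
    expect_gte(re$se_pooled, fe$se_pooled - 1e-14)
    # Q <= df implies the random-effects fit collapses onto fixed
    if (fe$het$Q <= fe$het$df) {
      expect_equal(re$y_pooled, fe$y_pooled, tolerance = 1e-12)
      expect_equal(re$se_pooled, fe$se_pooled, tolerance = 1e-12)
    }
  }
  # all-equal estimates: no heterogeneity at all
  fit <- meta_pool(rep(1.3, 5), runif(5, 0.1, 1))
  expect_equal(fit$het$Q, 0, tolerance = 1e-20)
  expect_identical(fit$het$i2, 0)
})

test_that("natural-scale CI round-trips through the analysis scale", {
  set.seed(31)
  for (i in 1:50) {
    k <- sample(1:6, 1)
    y <- rnorm(k)
    se <- runif(k, 0.05, 1)
    zq <- qnorm(0.975)
    trials <- lapply(seq_len(k), function(j)
      trial_effect(paste0("t", j), "RR", exp(y[j]),
                   exp(y[j] - zq * se[j]), exp(y[j] + zq * se[j])))
    effects <- lapply(trials, to_analysis_scale)
    fit <- pool_fixed(effects)
    expect_equal(log(fit$ci_lower), fit$y_pooled - zq * fit$se_pooled,
                 tolerance = 1e-10)
    expect_equal(log(fit$ci_upper), fit$y_pooled + zq * fit$se_pooled,
                 tolerance = 1e-10)
    # the generating (y, se) survive the natural-scale round trip
    for (j in seq_len(k)) {
      expect_equal(effects[[j]]$y, y[j], tolerance = 1e-10)
      expect_equal(effects[[j]]$se, se[j], tolerance = 1e-10)
    }
  }
})

test_that("pooling rejects degenerate inputs", {
  expect_error(meta_pool(numeric(0), numeric(0)), "no trials")
  expect_error(meta_pool(c(0, 1), c(0.5, 0)), "infinite weight")
  expect_error(meta_pool(c(0, 1), c(-0.5, 1)), "negative")
  expect_error(pool_fixed(list(
    to_analysis_scale(trial_effect("a", "RR", 1, 0.5, 2)),
    to_analysis_scale(trial_effect("b", "MD", 0, -1, 1)))),
    "mixed")
})

test_that("meta_pool methods expose the fit consistently", {
  fit <- meta_pool(c(0, 0, 0.6), c(1, 1, 0.5), scale = "log")
  expect_equal(unname(coef(fit)), fit$y_pooled)
  ci <- confint(fit)
  expect_equal(unname(ci["lower"]), fit$ci_lower, tolerance = 1e-14)
  expect_equal(weights(fit), fit$weights)
  expect_equal(residuals(fit), fit$y - fit$y_pooled)
  expect_output(print(fit), "Fixed-effect")
  expect_output(print(summary(fit)), "weight fractions")
})
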