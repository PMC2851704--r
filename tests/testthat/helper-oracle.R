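# Brute-force inverse-variance pooling, coded independently of the package
# (explicit loops, no shared helpers) for oracle-equivalence checks.
bf_pool <- function(y, se, model = "fixed") {
  k <- length(y)
  wi <- numeric(k)
  for (i in seq_len(k)) wi[i] <- 1 / (se[i] * se[i])
  num <- 0; den <- 0
  for (i in seq_len(k)) { num <- num + wi[i] * y[i]; den <- den + wi[i] }
  yf <- num / den
  Q <- 0
  for (i in seq_len(k)) Q <- Q + wi[i] * (y[i] - yf) * (y[i] - yf)
  if (k == 1) Q <- 0   # convention: no heterogeneity from one trial
  df <- k - 1
  sw2 <- 0
  for (i in seq_len(k)) sw2 <- sw2 + wi[i] * wi[i]
  C <- den - sw2 / den
  tau2 <- if (df == 0 || C <= 0) 0 else (Q - df) / C
  if (tau2 < 0) tau2 <- 0
  i2 <- if (Q <= 0) 0 else 100 * max(0, (Q - df) / Q)
  if (model == "random") {
    for (i in seq_len(k)) wi[i] <- 1 / (se[i] * se[i] + tau2)
    num <- 0; den <- 0
    for (i in seq_len(k)) { num <- num + wi[i] * y[i]; den <- den + wi[i] }
  }
  est <- num / den
  sep <- sqrt(1 / den)
  list(est = est, se = sep, p = 2 * pnorm(-abs(est) / sep),
       Q = Q, tau2 = tau2, i2 = i2, wfrac = wi / den)
}

# random small pooling instances under a fixed seed
random_instances <- function(n, seed, kmax = 8) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    k <- sample(1:kmax, 1)
    list(y = rnorm(k, sd = 2), se = runif(k, 0.05, 2))
  })
}

# compact per-trial fingerprint for determinism comparisons
write_review_signature <- function(rv) {
  vapply(rv$trials, function(t) sprintf("%s|%.15g|%.15g|%.15g",
                                        t$trial_id, t$point, t$ci_lower,
                                        t$ci_upper), character(1))
}

# a review with one dominant trial and a few imprecise ones
dominant_review <- function(id, se_big, se_rest, y = 0.4, k_rest = 3) {
  zq <- qnorm(0.975)
  tr <- function(tid, yy, ss, n) {
    trial_effect(tid, "MD", yy, yy - zq * ss, yy + zq * ss, n = n)
  }
  trials <- c(list(tr(paste0(id, "-t1"), y, se_big, 1000L)),
              lapply(seq_len(k_rest), function(j)
                tr(paste0(id, "-t", j + 1), y + 0.1 * j, se_rest, 50L)))
  review_outcome(id, "o", trials, model = "fixed")
}
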