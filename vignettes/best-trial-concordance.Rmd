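---
title: "Methods: pooling, concordance and the synthetic review corpus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooling, concordance and the synthetic review corpus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(besttrial)
```

## The question and the estimator

When no up-to-date systematic review exists, practitioners are sometimes
advised to rely on the single most informative randomized trial. The
operational definition used throughout this package is *the trial that
contributes the greatest inverse-variance weight to the meta-analysis* —
"most precise" rather than "largest", since weight tracks the width of the
confidence interval, not the sample size. The package's job is to quantify,
over a corpus of review outcomes, how often that trial and the full
meta-analysis reach the same statistical conclusion, and under what
circumstances they part ways.

Everything works from what reviews actually publish: a point estimate and
a 95% confidence interval per trial. Ratio measures (RR, OR, HR — grouped
together, all analysed identically) are mapped to the log scale; mean
differences stay on the identity scale. The standard error is recovered
assuming the interval is symmetric on the analysis scale,

$$\mathrm{se} = \frac{g(u) - g(\ell)}{2\,z_{1-\alpha/2}},$$

with the *exact* standard-normal quantile ($z_{0.975} = 1.959964\ldots$),
not the rounded 1.96. `to_analysis_scale(..., z_quantile = 1.96)` exists as
a compatibility flag for intervals that were themselves produced with the
rounded constant; internal consistency is the default because every
p-value downstream is computed with the same quantile function. Which
symmetry convention the original review software used per measure is not
knowable from the published interval alone; the symmetric-on-analysis-scale
assumption is the standard reconstruction and is used uniformly.

## Pooling and heterogeneity

`meta_pool()` implements the two standard inverse-variance estimators.
Fixed-effect: $w_i = 1/\mathrm{se}_i^2$, $\hat y = \sum w_i y_i / \sum
w_i$, $\mathrm{se}(\hat y) = (\sum w_i)^{-1/2}$. Heterogeneity:
$Q = \sum w_i (y_i - \hat y)^2$ on $k-1$ df, the method-of-moments
between-trial variance $\hat\tau^2 = \max\{0, (Q - df)/C\}$ with
$C = \sum w - \sum w^2 / \sum w$, and $I^2 = \max\{0, (Q-df)/Q\} \cdot
100$. Random effects (DerSimonian–Laird) re-weights by
$1/(\mathrm{se}_i^2 + \hat\tau^2)$.

Numerical conventions, all of which matter at the edges:

* **Single trial** (`k = 1`): the pooled result *is* the trial,
  bit-for-bit, with $Q = df = \tau^2 = I^2 = 0$ by convention.
* **$Q \le df$**: $\hat\tau^2 = 0$ and the random-effects fit collapses
  exactly onto the fixed-effect fit; $I^2 = 0$ (also when $Q = 0$).
* **Zero standard error**: rejected in multi-trial pooling (it would carry
  infinite weight and the data are certainly degenerate); allowed for a
  lone trial, where the pooled p-value takes its continuity-limit value
  (1 at the null, 0 off it). The standalone `z_pvalue()` keeps the strict
  contract and errors instead, since a caller asking for a z-test with
  `se = 0` off the null has a data problem worth surfacing.
* **CIs and p-values** use the plain normal approximation on the pooled
  standard error under both models — the behaviour of the software used to
  produce the source reviews — rather than a Knapp–Hartung-type
  adjustment, so recomputed and published results are comparable.

The test suite checks this engine two independent ways: against a
loop-coded brute-force implementation of the same formulas (to 1e-10 on
1000 random instances with $k \le 8$), and against `metafor::rma()` with
`method = "FE"` / `"DL"`.

## The concordance pipeline

`build_concordance()` pools each review outcome under the model its
authors declared (the pipeline never second-guesses that choice; an
optional `pooled_override` accepts summary-only reviews), identifies the
most precise trial under the same model, recomputes that trial's two-sided
z-test p-value on the analysis scale, and classifies the pair at
$\alpha = 0.05$ with a *strict* inequality — a boundary p-value of exactly
0.05 is non-significant, matching the "less than 0.05" dichotomization
convention.

Design choices where the problem is genuinely open:

* **Weight ties** are broken by larger sample size, then input order —
  deterministic and the closest thing to "the bigger trial" a human
  extractor would pick.
* **Single-trial reviews** are classified `single_trial_sig` /
  `single_trial_nonsig`. They sit on the agreement diagonal by
  construction (the "meta-analysis" is the trial), and the agreement table
  reports them as sub-counts of the diagonal cells rather than mixing them
  silently into multi-trial agreement.
* **Rank correlation** between trial and pooled estimates is Spearman's
  rho (Pearson applied to mid-ranks is Spearman by definition).
  Ratio and difference outcomes live on different scales, so
  `estimate_rank_correlation()` reports per-class correlations, plus a
  combined `"standardized"` class that divides each analysis-scale
  estimate by its standard error before ranking; scales are never mixed
  silently.
* **Direction of effect** is `neutral` only when the analysis-scale
  estimate equals the null exactly; otherwise `favors`/`against` via the
  declared `direction_of_benefit`, which is metadata and never touches a
  p-value.
* **Rates are always derived from counted cells.** Narrative agreement
  percentages attached to published 2×2 tables are occasionally
  inconsistent with the tables themselves; `conditional_rates()` therefore
  recomputes everything from its own `agreement_table()`, and a zero
  denominator yields an explicit `NA` marker rather than a crash.
* Reviews that cannot be pooled are excluded upstream with a per-review
  logged reason, so corpus accounting ("n evaluable of N") is auditable.

`discrepancy_report()` lists the `trial_sig_only` records with both
p-values, both estimates, the weight share and $I^2$ — the cases worth a
reviewer's attention, since in practice they coincide with marked
between-trial heterogeneity. `stratify_by_weight()` splits records at a
weight-share threshold (default 50%) and emits the paired
estimate–estimate and p–p point sets for scatter displays.

## The synthetic corpus

No machine-readable corpus of hand-extracted review outcomes is available,
so `simulate_corpus()` generates one with known truth. Generation is at
the estimate level — the minimal structure the pipeline consumes:

1. trial count: single-trial with probability 35/167, else
   $k = 2 + \mathrm{NegBin}(\text{size}=0.4, \mu=5.3)$;
2. trial sizes: hierarchical log-normal — a review-level location
   $\mu_r \sim N(\log 183,\, 1.62^2)$ and per-trial
   $\log n_i \sim N(\mu_r,\, 1.0^2)$, floored at $n = 10$;
3. precision: $\mathrm{se}_i = c/\sqrt{n_i}$ with $c = 2$;
4. effects: $\theta_i \sim N(\theta, \tau^2)$,
   $y_i \sim N(\theta_i, \mathrm{se}_i^2)$, with defaults
   $\theta = \log 0.8$, $\tau = 0.05$;
5. intervals back-computed from $\mathrm{se}_i$ at the configured level,
   so generated trials round-trip through `to_analysis_scale()` to their
   generating standard errors exactly.

The defaults are calibrated to the descriptive statistics of a large
hand-extracted sample of reviews: median 4 and mean ≈ 7.3 trials per
meta-analysis, ~21% single-trial reviews, median trial size 183 with a
heavy upper tail (marginal log-sd ≈ 1.9), and — via the within-review size
spread, tuned once by Monte Carlo — a median largest-trial weight share
near 51%. The between-trial SD default $\tau = 0.05$ puts the median
$I^2$ near zero with a long tail; a single global $\tau$ cannot match both
the median and the mean of a real corpus's $I^2$ distribution (real
heterogeneity is concentrated in a minority of reviews), and the median is
prioritised. `model_policy` defaults to `always_fixed`; `"by_Q"` mimics
review-author behaviour by switching to random effects when $Q$ is
significant at 0.10.

Reproducibility: one global seed; review $i$ draws from a documented
substream, `(seed * 48271 + 7919 i) mod (2^31 − 1)`, so a corpus is
byte-identical across runs and individual reviews can be regenerated in
isolation or in parallel.

What the generator deliberately does *not* emulate: binomial 2×2 event
counts (estimates are exactly normal, so normal-theory coverage is exact
by construction — coverage checks validate the pipeline arithmetic, not
the normal approximation for sparse data), publication bias and
small-study effects, correlation between effect size and trial size,
clinically heterogeneous interventions within a review, and outcome
selection. Passing calibration and recovery tests therefore show that the
machinery is correct and the corpus shape realistic, not that real
extracted corpora would behave identically.

## Validation problem sizes

The shipped checks use, as the package's own choices: 1000 random
instances ($k \le 8$) for oracle equivalence; 5000-review corpora for
calibration medians and weight-share-stratified agreement; 2000-review
homogeneous corpora for recovery (bias within 3 Monte-Carlo SEs, 95% CI
coverage, type-I error at the null within 3 binomial SEs). A 161-outcome
deterministic fixture (`synthetic_concordance_corpus()`) pins the
agreement-table arithmetic: cells 55/5/31/70 with 14 and 15 single-trial
reviews on the diagonal, conditional rates 55/60 and 31/101, and a
5-row discrepancy report whose rows all show $I^2 > 0$.

## Known limitations

* Works from estimate + CI only; no access to event counts means no
  Peto/Mantel–Haenszel pooling, no continuity corrections, and no way to
  detect asymmetric intervals that were not normal-theory to begin with.
* DerSimonian–Laird is the only random-effects estimator, chosen to match
  standard review tooling; REML/profile-likelihood alternatives are out of
  scope.
* The agreement analysis treats the meta-analysis as the reference
  standard, which is itself a debatable convention — the package measures
  concordance, not correctness.
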