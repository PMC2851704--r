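zq <- qnorm(0.975)

md_trial <- function(id, y, se, n = NA_integer_) {
  trial_effect(id, "MD", y, y - zq * se, y + zq * se, n = n)
}
md_review <- function(id, y, se, n = rep(NA_integer_, length(y)),
                      model = "fixed") {
  review_outcome(id, "o", lapply(seq_along(y), function(j)
    md_trial(paste0(id, "-t", j), y[j], se[j], n[j])), model = model)
}

test_that("the most precise trial is the one with the greatest weight", {
  rv <- md_review("r1", c(0.1, 0.2, 0.3), c(1, 0.5, 2))
  mp <- most_precise_trial(rv)
  expect_identical(mp$index, 2L)
  expect_equal(mp$weight_share, 4 / 5.25, tolerance = 1e-12)

  # single trial owns all the weight
  mp <- most_precise_trial(md_review("r2", 0.4, 0.3))
  expect_identical(mp$index, 1L)
  expect_identical(mp$weight_share, 1)

  # exact tie on weight: larger n wins, then input order
  rv <- md_review("r3", c(0.1, 0.2), c(0.5, 0.5), n = c(100L, 200L))
  expect_identical(most_precise_trial(rv)$index, 2L)
  rv <- md_review("r4", c(0.1, 0.2), c(0.5, 0.5))
  expect_identical(most_precise_trial(rv)$index, 1L)
})

test_that("significance is dichotomized strictly at alpha", {
  expect_true(classify_significance(0.04))
  expect_false(classify_significance(0.05))   # boundary is non-significant
  expect_false(classify_significance(1.0))
  expect_error(classify_significance(-0.1), "0, 1")
  expect_error(classify_significance(1.1), "0, 1")
  # monotone: anything below a significant p is significant
  p <- sort(runif(50))
  sig <- classify_significance(p)
  expect_true(all(diff(as.integer(sig)) <= 0))
})

test_that("concordance records pair the trial with its meta-analysis faithfully", {
  # duplicated trial: same pooled estimate, never a larger p
  rv1 <- md_review("a", 0.35, 0.2)
  rv2 <- md_review("b", c(0.35, 0.35), c(0.2, 0.2))
  r1 <- build_concordance(rv1)
  r2 <- build_concordance(rv2)
  expect_equal(r2$meta_y, r1$meta_y, tolerance = 1e-14)
  expect_lte(r2$meta_p, r2$trial_p)
  expect_identical(r1$agreement_class, "single_trial_nonsig")
  expect_identical(r1$weight_share, 1)
  expect_identical(r1$k, 1L)

  # duplicating every trial m times: estimate invariant, p non-increasing
  y <- c(0.1, 0.4, -0.2); se <- c(0.3, 0.2, 0.5)
  base <- build_concordance(md_review("c", y, se))
  for (m in 2:3) {
    dup <- build_concordance(md_review("d", rep(y, m), rep(se, m)))
    expect_equal(dup$meta_y, base$meta_y, tolerance = 1e-12)
    expect_lte(dup$meta_p, base$meta_p + 1e-14)
  }

  # significant trial inside a heterogeneous, null pooled result
  rv <- md_review("e", c(0.5, -0.5), c(0.2, 0.25))
  r <- build_concordance(rv)
  expect_true(r$trial_sig)
  expect_false(r$meta_sig)
  expect_identical(r$agreement_class, "trial_sig_only")
  expect_gt(r$i2, 0)

  # single significant trial
  r <- build_concordance(md_review("f", 0.5, 0.2))
  expect_identical(r$agreement_class, "single_trial_sig")

  # directions: neutral exactly at the null, otherwise via declared benefit side
  r <- build_concordance(md_review("g", 0, 0.2))
  expect_identical(r$trial_direction, "neutral")
  r <- build_concordance(md_review("h", -0.3, 0.2))
  expect_identical(r$trial_direction, "favors")  # less_than_null default
  expect_identical(r$meta_direction, "favors")
})

test_that("a dominant trial forces the meta-analysis to its own p-value", {
  for (se_big in c(0.01, 0.02)) {
    rv <- dominant_review("dom", se_big = se_big, se_rest = 3)
    r <- build_concordance(rv)
    expect_gt(r$weight_share, 0.999)
    expect_lt(abs(r$trial_p - r$meta_p), 0.01)
  }
})

test_that("agreement table counts and conditional rates are consistent", {
  # empty input: a zero table, no crash
  cc <- concordance(list())
  expect_identical(cc$table$total, 0L)
  expect_identical(cc$table$n11 + cc$table$n10 + cc$table$n01 + cc$table$n00,
                   0L)
  expect_true(is.na(cc$rates$overall_agreement))

  # all both_sig: only n11 populated
  revs <- lapply(1:4, function(i) md_review(paste0("s", i),
                                            c(0.5, 0.5), c(0.1, 0.12)))
  tab <- concordance(revs)$table
  expect_identical(tab$n11, 4L)
  expect_identical(tab$n10 + tab$n01 + tab$n00, 0L)

  # cells always partition the records; rates live in [0, 1]
  cc <- concordance(synthetic_concordance_corpus())
  tab <- cc$table
  expect_identical(tab$n11 + tab$n10 + tab$n01 + tab$n00, nrow(cc$records))
  for (r in unlist(cc$rates)) if (!is.na(r)) {
    expect_gte(r, 0); expect_lte(r, 1)
  }
  # zero denominator yields the explicit undefined marker
  rates <- conditional_rates(agreement_table(
    cc$records[cc$records$trial_sig, , drop = FALSE]))
  expect_true(is.na(rates$p_meta_sig_given_trial_nonsig))
  expect_false(is.na(rates$p_meta_sig_given_trial_sig))
})

test_that("rank correlation is Spearman on the requested measure class", {
  mk <- function(ty, my, i) data.frame(
    review_id = paste0("r", i), outcome_name = "o", k = 2L,
    measure_class = "difference", trial_id = "t", trial_y = ty,
    trial_se = 1, trial_p = 0.5, meta_y = my, meta_se = 0.5, meta_p = 0.5,
    trial_estimate = ty, meta_estimate = my, weight_share = 0.6, i2 = 0,
    trial_sig = FALSE, meta_sig = FALSE, agreement_class = "both_nonsig",
    trial_direction = "favors", meta_direction = "favors",
    stringsAsFactors = FALSE)
  recs <- do.call(rbind, Map(mk, 1:5, c(2, 4, 6, 8, 10), 1:5))
  expect_equal(estimate_rank_correlation(recs, "difference"), 1)
  recs_rev <- do.call(rbind, Map(mk, 1:5, c(10, 8, 6, 4, 2), 1:5))
  expect_equal(estimate_rank_correlation(recs_rev, "difference"), -1)
  # one swapped pair: frozen at 0.9, from explicit rank-and-correlate
  recs_swap <- do.call(rbind, Map(mk, 1:5, c(1, 2, 4, 3, 5), 1:5))
  expect_equal(estimate_rank_correlation(recs_swap, "difference"), 0.9,
               tolerance = 1e-12)
  # standardized class divides by the standard errors before ranking
  expect_equal(estimate_rank_correlation(recs_swap, "standardized"), 0.9,
               tolerance = 1e-12)
  expect_error(estimate_rank_correlation(recs[1:2, ], "difference"),
               "at least 3")
  expect_error(estimate_rank_correlation(recs, "ratio"), "at least 3")
})

test_that("CI relationship flags containment and overlap", {
  t1 <- trial_effect("t", "RR", 1.0, 0.5, 2.0)
  mk_pool <- function(est, lo, hi) structure(
    list(estimate = est, ci_lower = lo, ci_upper = hi, scale = "log"),
    class = "meta_pool")
  r <- ci_relationship(t1, mk_pool(1.9, 1.8, 3.0))
  expect_true(r$contains_pooled_estimate)
  expect_true(r$intervals_overlap)
  # identical intervals
  r <- ci_relationship(t1, mk_pool(1.0, 0.5, 2.0))
  expect_true(r$contains_pooled_estimate && r$intervals_overlap)
  # disjoint
  r <- ci_relationship(t1, mk_pool(3.0, 2.5, 4.0))
  expect_false(r$contains_pooled_estimate)
  expect_false(r$intervals_overlap)
  # scale mismatch is an error, not a silent comparison
  md_pool <- structure(list(estimate = 0, ci_lower = -1, ci_upper = 1,
                            scale = "identity"), class = "meta_pool")
  expect_error(ci_relationship(t1, md_pool), "different scales")
})

test_that("discrepancy report lists exactly the trial-significant-only records", {
  cc <- concordance(synthetic_concordance_corpus())
  d <- discrepancy_report(cc)
  expect_identical(nrow(d), cc$table$n10)
  expect_true(all(d$trial_p < 0.05 & d$meta_p >= 0.05))
  expect_true(all(d$i2 > 0))
  expect_identical(d$review_id, sort(d$review_id))
  expect_named(d, c("review_id", "outcome_name", "k", "meta_p", "trial_p",
                    "weight_share", "meta_estimate", "trial_estimate", "i2"))
  # concordant corpus: empty report
  revs <- lapply(1:3, function(i) md_review(paste0("c", i),
                                            c(0.5, 0.5), c(0.1, 0.12)))
  expect_identical(nrow(discrepancy_report(concordance(revs)$records)), 0L)
})

test_that("weight-share stratification partitions records and exports scatter sets", {
  cc <- concordance(synthetic_concordance_corpus())
  st <- stratify_by_weight(cc$records)
  expect_identical(sum(st$summary$n), nrow(cc$records))
  expect_identical(nrow(st$points$estimates), nrow(cc$records))
  expect_identical(nrow(st$points$pvalues), nrow(cc$records))
  # threshold 0: single-trial reviews (share 1) aside, everything is one
  # stratum and its agreement equals the overall rate
  st0 <- stratify_by_weight(cc$records, threshold = 0)
  expect_identical(st0$summary$n[2], 0L)
  expect_equal(st0$summary$agreement_rate[1], cc$rates$overall_agreement,
               tolerance = 1e-12)
  # all single trials: one nonempty stratum, perfect agreement
  singles <- lapply(1:4, function(i) md_review(paste0("s", i), 0.2, 0.3))
  st1 <- stratify_by_weight(concordance(singles)$records)
  expect_identical(st1$summary$n, c(4L, 0L))
  expect_equal(st1$summary$agreement_rate[1], 1)
})
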