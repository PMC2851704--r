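#' Synthetic fixture corpus with a known agreement pattern
#'
#' A deterministic, fully synthetic corpus of 161 review outcomes engineered
#' so that the concordance pipeline classifies them into a known 2x2
#' agreement pattern: 55 where both the most precise trial and the
#' meta-analysis are significant (14 of them single-trial reviews), 5 where
#' only the trial is significant (each with marked between-trial
#' heterogeneity), 31 where only the meta-analysis is significant, and 70
#' where neither is (15 single-trial). It is a regression fixture for the
#' agreement table, the conditional rates and the discrepancy report — a
#' synthetic stand-in constructed in code, not extracted review data.
#'
#' Reviews alternate between ratio (RR) and difference (MD) outcomes, and a
#' small deterministic offset varies the estimates within each block without
#' crossing any significance boundary.
#'
#' @return A list of [review_outcome()] objects.
#' @examples
#' cc <- concordance(synthetic_concordance_corpus())
#' cc$table
#' @export
synthetic_concordance_corpus <- function() {
  zq <- ci_quantile(0.95)
  idx <- 0L
  reviews <- list()

  make_trial <- function(id, ratio, y, se, n) {
    lo <- y - zq * se
    hi <- y + zq * se
    if (ratio)
      trial_effect(id, "RR", exp(y), exp(lo), exp(hi), n = n)
    else
      trial_effect(id, "MD", y, lo, hi, n = n)
  }
  add_review <- function(ys, ses, ns) {
    idx <<- idx + 1L
    rid <- sprintf("SR%03d", idx)
    ratio <- idx %% 2L == 0L
    trials <- lapply(seq_along(ys), function(j)
      make_trial(sprintf("%s-t%d", rid, j), ratio, ys[j], ses[j], ns[j]))
    reviews[[length(reviews) + 1L]] <<-
      review_outcome(rid, "primary outcome", trials, model = "fixed")
  }
  eps <- function(i) 0.002 * (i %% 5L)

  # both significant, two trials
  for (i in 1:41) add_review(c(0.5 + eps(i), 0.45 + eps(i)),
                             c(0.15, 0.16), c(400L, 350L))
  # single-trial, significant
  for (i in 1:14) add_review(0.5 + eps(i), 0.2, 100L)
  # trial significant, meta-analysis not (heterogeneous pairs)
  for (i in 1:5) add_review(c(0.5 + eps(i), -0.5 + eps(i)),
                            c(0.2, 0.25), c(150L, 80L))
  # meta-analysis significant, trial not (three concordant modest trials)
  for (i in 1:31) add_review(c(0.3 + eps(i), 0.3, 0.3),
                             c(0.18, 0.18, 0.18), c(300L, 200L, 100L))
  # neither significant, two trials
  for (i in 1:55) add_review(c(0.1 + eps(i), 0.05),
                             c(0.2, 0.22), c(150L, 120L))
  # single-trial, non-significant
  for (i in 1:15) add_review(0.1 + eps(i), 0.2, 90L)

  reviews
}
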