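test_that("Bonferroni bookkeeping is exact arithmetic", {
  bc <- bonferroni_alpha(0.05, 43)
  expect_equal(bc$alpha_c, 0.05 / 43)
  expect_equal(bc$alpha_c_4dp, 0.0011)
  expect_equal(bc$ci_level_percent, 99.88)
  bc1 <- bonferroni_alpha(0.05, 1)
  expect_equal(bc1$alpha_c, 0.05)
  expect_equal(bc1$ci_level_percent, 95.00)
  bc10 <- bonferroni_alpha(0.01, 10)
  expect_equal(bc10$alpha_c, 0.001)
  expect_equal(bc10$ci_level_percent, 99.90)
  expect_error(bonferroni_alpha(0.05, 0), "positive comparison count")
  expect_error(bonferroni_alpha(1.5, 10), "alpha")
})

test_that("opt-in resampling returns n records drawn from the original multiset", {
  set.seed(1)
  ds <- toy_panel(runif(20) < 0.5, w = runif(20, 0.5, 2))
  rep1 <- resample_survey(ds, seed = 5)
  expect_equal(nrow(rep1$data), 20)
  expect_true(all(rep1$data$respondent_id %in% ds$data$respondent_id))
  # identical seed, identical replicate
  expect_identical(rep1$data, resample_survey(ds, seed = 5)$data)
  expect_false(identical(rep1$data, resample_survey(ds, seed = 6)$data))
})

test_that("PSU resampling draws n_h clusters per stratum with expected inclusion 1", {
  ds <- toy_clustered(rep(1:2, each = 6), rep(1:4, each = 3),
                      rep(c(TRUE, FALSE), 6))
  counts <- vapply(seq_len(4000), function(b) {
    r <- resample_survey(ds, seed = b, unit = "psu")
    # PSU 1 of stratum 1 appears in k relabeled copies
    sum(grepl("^1\\.", r$data$psu[r$data$stratum == 1])) / 3
  }, numeric(1))
  # per-replicate inclusion count is Binomial(n_h = 2, 1/2) with mean 1
  expect_lt(abs(mean(counts) - 1), 3 * sd(counts) / sqrt(length(counts)))
  # each stratum keeps n_h PSUs per replicate (weight-preserving copies)
  r <- resample_survey(ds, seed = 1, unit = "psu")
  expect_equal(nrow(r$data), 12)
  expect_equal(length(unique(r$data$psu[r$data$stratum == 1])), 2)
})

test_that("degenerate single-PSU designs are rejected by dataset validation", {
  expect_error(toy_clustered(rep(1, 4), rep(1, 4), c(T, F, T, F)),
               "single sampled PSU")
})

test_that("bootstrap differences equal an independently coded resample-estimate-subtract loop", {
  set.seed(2)
  ds_a <- toy_panel(runif(20) < 0.4, w = runif(20, 0.5, 2))
  ds_b <- toy_panel(runif(20) < 0.6, w = runif(20, 0.5, 2))
  est <- function(ds) weighted_proportion(ds, function(d) d$y)$p_hat
  B <- 50; seed <- 77
  diffs <- bootstrap_differences(ds_a, ds_b, est, B = B, seed = seed)
  # independent oracle following the documented child-seed protocol
  oracle <- vapply(seq_len(B), function(b) {
    set.seed(child_seed(seed, b, "A"))
    ia <- sample.int(20, 20, replace = TRUE)
    set.seed(child_seed(seed, b, "B"))
    ib <- sample.int(20, 20, replace = TRUE)
    wa <- ds_a$data$weight[ia]; ya <- ds_a$data$y[ia]
    wb <- ds_b$data$weight[ib]; yb <- ds_b$data$y[ib]
    sum(wb * yb) / sum(wb) - sum(wa * ya) / sum(wa)
  }, numeric(1))
  expect_equal(as.numeric(diffs), oracle, tolerance = 1e-14)
  # the vectorized proportion engine consumes the same replicate streams
  fast <- dualsurvey:::bootstrap_proportion_differences(
    ds_a, ds_b, list(q = function(d) d$y), B = B, seed = seed)
  expect_equal(as.numeric(fast), oracle, tolerance = 1e-14)
})

test_that("a constant estimator yields all-zero differences; self-comparison centers at 0", {
  set.seed(3)
  ds <- toy_panel(runif(200) < 0.3)
  const <- bootstrap_differences(ds, ds, function(d) 0.42, B = 20, seed = 1)
  expect_true(all(const == 0))
  est <- function(d) weighted_proportion(d, function(x) x$y)$p_hat
  diffs <- bootstrap_differences(ds, ds, est, B = 200, seed = 9)
  se_boot <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se_boot)
})

test_that("failed replicates are excluded and a >5% failure rate is a hard error", {
  set.seed(4)
  ds <- toy_panel(runif(50) < 0.5)
  flaky <- local({
    calls <- 0
    function(d) {
      calls <<- calls + 1
      if (calls %% 30 == 0) stop("empty cell")
      weighted_proportion(d, function(x) x$y)$p_hat
    }
  })
  diffs <- bootstrap_differences(ds, ds, flaky, B = 40, seed = 2)
  expect_lte(attr(diffs, "n_excluded"), 2)
  # fails on every replicate (but not on the sizing call)
  fail_after_first <- local({
    calls <- 0
    function(d) {
      calls <<- calls + 1
      if (calls > 1) stop("boom")
      0.5
    }
  })
  expect_error(bootstrap_differences(ds, ds, fail_after_first, B = 20, seed = 2),
               "> 5%")
})

test_that("difference summaries match hand-computed interpolated quantiles", {
  # degenerate distribution collapses to the point
  s0 <- summarize_difference(rep(2.5, 100), alpha = 0.05, m = 1)
  expect_equal(s0$diff_point, 2.5)
  expect_equal(c(s0$ci_low, s0$ci_high, s0$cci_low, s0$cci_high),
               rep(2.5, 4))
  # diffs 1..100: interpolated inverse-ECDF quantiles at 0.025 / 0.975 by
  # hand: h = n p = 2.5 -> x(2) + 0.5 = 2.5; h = 97.5 -> x(97) + 0.5 = 97.5
  s <- summarize_difference(as.numeric(1:100), alpha = 0.05, m = 1)
  expect_equal(s$diff_point, 50.5)
  expect_equal(s$ci_low, 2.5, tolerance = 1e-12)
  expect_equal(s$ci_high, 97.5, tolerance = 1e-12)
  # corrected interval at m = 43 is the 99.88% percentile interval
  s43 <- summarize_difference(as.numeric(1:100), alpha = 0.05, m = 43)
  a_c <- 0.05 / 43
  expect_equal(s43$alpha_c, a_c)
  expect_equal(s43$cci_low,
               unname(quantile(as.numeric(1:100), a_c / 2, type = 4)),
               tolerance = 1e-12)
  expect_true(s43$cci_low <= s43$ci_low && s43$cci_high >= s43$ci_high)
})

test_that("corrected intervals always contain the uncorrected ones", {
  set.seed(6)
  for (i in 1:25) {
    diffs <- rnorm(300, mean = runif(1, -2, 2), sd = runif(1, 0.1, 3))
    s <- summarize_difference(diffs, alpha = 0.05, m = sample(2:50, 1))
    expect_lte(s$cci_low, s$ci_low)
    expect_gte(s$cci_high, s$ci_high)
    expect_gte(s$diff_point, min(diffs))
    expect_lte(s$diff_point, max(diffs))
  }
})

test_that("compare_surveys is deterministic and reports the B-minus-A convention", {
  d <- raw_survey_frame(150, seed = 8)
  ds_a <- harmonize_survey(survey_dataset(d, kind = "optin_panel"))
  d2 <- raw_survey_frame(150, seed = 9)
  ds_b <- harmonize_survey(survey_dataset(d2, kind = "optin_panel"))
  qs <- default_quantities()[c("either.past_year", "heroin.past_year")]
  r1 <- compare_surveys(ds_a, ds_b, quantities = qs, B = 60, seed = 5)
  r2 <- compare_surveys(ds_a, ds_b, quantities = qs, B = 60, seed = 5)
  expect_identical(r1, r2)
  # plain difference column follows the caption rule: survey B minus survey A
  expect_equal(r1$diff_plain, r1$est_b - r1$est_a, tolerance = 1e-12)
  man <- attr(r1, "manifest")
  expect_equal(man$sign_convention, "survey B minus survey A")
  expect_equal(man$B, 60)
  expect_error(compare_surveys(ds_a, ds_b, quantities = qs, B = 10, seed = 1,
                               m = 1), "smaller than")
})
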