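# Simulation experiments that score the cross-survey machinery against known
# truth: family-wise error control of the corrected bootstrap intervals under
# a null, coverage and bias for a true cross-survey difference, and Wald
# coverage of the survey-weighted logistic fit. These are the package's
# calibration studies; the analysis drivers and the acceptance checks run
# them at stated sizes.

#' Family-wise error of corrected intervals under a cross-survey null
#'
#' Each simulated family draws two surveys of size `n` from one population
#' with `m` binary outcomes of equal prevalence in both surveys (so every
#' true difference is zero): survey A as a stratified clustered sample
#' (PSU-bootstrap resampling; cluster labels carry no effects, and the
#' number of PSUs per stratum is large enough that the uncorrected
#' with-replacement bootstrap's (n_h - 1)/n_h variance deflation is
#' negligible), survey B as a panel (respondent resampling). The family's
#' Bonferroni-corrected percentile intervals are computed and the family
#' counts as an error if at least one corrected interval excludes zero.
#'
#' @param n_families simulated families.
#' @param n respondents per survey.
#' @param m comparison-family size (outcomes per family).
#' @param B bootstrap replicates per family.
#' @param alpha family-wise level.
#' @param seed master seed.
#' @param prevalences length-`m` vector of true outcome prevalences.
#' @param n_strata,psus_per_stratum cluster structure of survey A.
#' @return list: `familywise_error_rate`, `n_families`, `mc_se`, and the
#'   per-family error flags.
#' @export
simulate_null_calibration <- function(n_families = 200, n = 5000, m = 10,
                                      B = 500, alpha = 0.05, seed = 1,
                                      prevalences = seq(0.04, 0.22,
                                                        length.out = m),
                                      n_strata = 5, psus_per_stratum = 40) {
  stopifnot(length(prevalences) == m)
  qs <- lapply(seq_len(m), function(j) {
    local({ j <- j; function(d) d[[paste0("y", j)]] })
  })
  names(qs) <- paste0("y", seq_len(m))
  one_family <- function(f) {
    set.seed(child_seed(seed, f, "family"))
    mk <- function(kind) {
      Y <- vapply(prevalences, function(pj) stats::runif(n) < pj, logical(n))
      colnames(Y) <- names(qs)
      d <- data.frame(respondent_id = seq_len(n), Y, weight = 1)
      if (kind == "probability_clustered") {
        d$stratum <- rep_len(seq_len(n_strata), n)
        d$psu <- sample(rep_len(seq_len(psus_per_stratum), n))
        survey_dataset(d, kind, stratum_col = "stratum", psu_col = "psu")
      } else survey_dataset(d, kind)
    }
    a <- mk("probability_clustered"); b <- mk("optin_panel")
    diffs <- bootstrap_proportion_differences(
      a, b, qs, B = B, seed = child_seed(seed, f, "boot"))
    for (j in seq_len(m)) {
      s <- summarize_difference(100 * diffs[, j], alpha = alpha, m = m)
      if (s$cci_low > 0 || s$cci_high < 0) return(TRUE)
    }
    FALSE
  }
  err <- vapply(seq_len(n_families), one_family, logical(1))
  rate <- mean(err)
  # Monte-Carlo SE of the estimated rate, computed at the estimate
  # (the standard simulation-study convention)
  list(familywise_error_rate = rate, n_families = n_families,
       mc_se = sqrt(rate * (1 - rate) / n_families), errors = err)
}

#' Coverage and bias for a true cross-survey prevalence difference
#'
#' Repeated experiments draw survey A with true prevalence `p_a` and survey B
#' with `p_b` (panel kind, respondent resampling), run the replicate
#' bootstrap, and score (i) whether the Bonferroni-corrected percentile
#' interval covers the true difference and (ii) the bootstrap-mean point
#' estimate's bias.
#'
#' @param n_experiments replicate experiments.
#' @param n respondents per survey.
#' @param p_a,p_b true prevalences (default differ by 0.5 percentage points).
#' @param B bootstrap replicates.
#' @param m comparison-family size used for the correction.
#' @param alpha family-wise level.
#' @param seed master seed.
#' @return list: `coverage` of the corrected interval, `nominal` coverage
#'   level, `mean_point` and `bias` (percentage points), `mc_se_point`,
#'   per-experiment points and coverage flags.
#' @export
simulate_difference_recovery <- function(n_experiments = 200, n = 5000,
                                         p_a = 0.005, p_b = 0.010,
                                         B = 1000, m = 10, alpha = 0.05,
                                         seed = 1) {
  delta <- 100 * (p_b - p_a)
  one_exp <- function(f) {
    set.seed(child_seed(seed, f, "exp"))
    mk <- function(p) survey_dataset(
      data.frame(respondent_id = seq_len(n), y = stats::runif(n) < p,
                 weight = 1), "optin_panel")
    a <- mk(p_a); b <- mk(p_b)
    diffs <- bootstrap_proportion_differences(
      a, b, list(y = function(d) d$y), B = B,
      seed = child_seed(seed, f, "boot"))
    s <- summarize_difference(100 * diffs[, 1], alpha = alpha, m = m)
    c(point = s$diff_point,
      covered = as.numeric(s$cci_low <= delta && delta <= s$cci_high))
  }
  res <- vapply(seq_len(n_experiments), one_exp, numeric(2))
  cvg <- mean(res["covered", ])
  list(coverage = cvg,
       mc_se_coverage = sqrt(cvg * (1 - cvg) / n_experiments),
       nominal = 1 - alpha / m,
       true_difference = delta,
       mean_point = mean(res["point", ]),
       bias = mean(res["point", ]) - delta,
       mc_se_point = stats::sd(res["point", ]) / sqrt(n_experiments),
       points = res["point", ], covered = res["covered", ] == 1)
}

#' Wald coverage of the survey-weighted logistic slope
#'
#' Replicates draw a binary predictor and a Bernoulli outcome from a known
#' logistic model, fit the survey-weighted logit with its design-based
#' sandwich covariance, and score whether the 95% Wald interval covers the
#' true slope.
#'
#' @param n_replicates simulation replicates.
#' @param n respondents per replicate.
#' @param beta0,beta1 true intercept and slope (log-odds).
#' @param level CI level.
#' @param seed master seed.
#' @return list: `coverage`, `n_replicates`, `mc_se`, per-replicate flags.
#' @export
simulate_regression_coverage <- function(n_replicates = 300, n = 800,
                                         beta0 = -1.2, beta1 = 0.8,
                                         level = 0.95, seed = 1) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  cov <- vapply(seq_len(n_replicates), function(r) {
    set.seed(child_seed(seed, r, "rep"))
    x <- factor(sample(c("no", "yes"), n, TRUE), levels = c("no", "yes"))
    eta <- beta0 + beta1 * (x == "yes")
    y <- stats::runif(n) < inv_logit(eta)
    ds <- survey_dataset(data.frame(respondent_id = seq_len(n), y = y,
                                    x = x, weight = 1), "optin_panel")
    fit <- fit_weighted_logit(ds, y ~ x)
    se <- sqrt(fit$cov["xyes", "xyes"])
    abs(fit$beta[["xyes"]] - beta1) <= z * se
  }, logical(1))
  rate <- mean(cov)
  list(coverage = rate, n_replicates = n_replicates,
       mc_se = sqrt(rate * (1 - rate) / n_replicates), covered = cov)
}
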