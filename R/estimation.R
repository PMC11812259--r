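# Design-based prevalence estimation: the weighted ratio estimator of a
# proportion, Taylor-linearized (ultimate-cluster, with-replacement first
# stage) standard errors, and logit-transformed confidence intervals.

#' Indicator for an outcome and recency window on harmonized records
#'
#' `past_year` means any use in the last 12 months (recency above `none`);
#' `past_month` and `months_2_12` are the two-level split within past-year
#' users.
#'
#' @param data harmonized respondent records.
#' @param outcome `"heroin"`, `"imf"` or `"either"`.
#' @param recency `"past_year"`, `"past_month"` or `"months_2_12"`.
#' @return logical vector, one element per record.
#' @export
outcome_indicator <- function(data, outcome, recency) {
  outcome <- match.arg(outcome, c("heroin", "imf", "either"))
  recency <- match.arg(recency, c("past_year", "past_month", "months_2_12"))
  col <- paste0(outcome, "_recency")
  if (!col %in% names(data)) fail("column '%s' missing; harmonize first", col)
  r <- as.character(data[[col]])
  switch(recency,
         past_year = r != "none",
         past_month = r == "past_month",
         months_2_12 = r == "months_2_12")
}

# Resolve an indicator argument (logical vector or function of the data).
resolve_indicator <- function(ds, indicator) {
  y <- if (is.function(indicator)) indicator(ds$data) else indicator
  if (!is.logical(y) || length(y) != nrow(ds$data) || anyNA(y)) {
    fail("indicator must yield a complete logical vector over the records")
  }
  y
}

#' Weighted proportion
#'
#' The design-based ratio estimator `sum(w*y) / sum(w)` over all records.
#'
#' @param ds a [survey_dataset()].
#' @param indicator logical vector over records, or a function of the record
#'   table returning one.
#' @return list with `p_hat`, `weighted_total` (sum of weights) and
#'   `n_unweighted` (record count).
#' @export
weighted_proportion <- function(ds, indicator) {
  stopifnot(inherits(ds, "survey_dataset"))
  y <- resolve_indicator(ds, indicator)
  w <- ds_weights(ds)
  tw <- sum(w)
  if (tw <= 0) fail("zero total weight")
  list(p_hat = sum(w * y) / tw, weighted_total = tw,
       n_unweighted = length(y))
}

# Ultimate-cluster variance of a weighted total of scores u_i:
# per-PSU totals z_hj, variance = sum_h n_h/(n_h-1) sum_j (z_hj - zbar_h)^2.
# For the opt-in kind each respondent is its own PSU in a single stratum.
# u may be a matrix (one column per score); returns the covariance matrix.
ultimate_cluster_var <- function(ds, u) {
  u <- as.matrix(u)
  if (ds$kind == "probability_clustered") {
    stratum <- as.character(ds$data[[ds$stratum_col]])
    psu <- paste(stratum, as.character(ds$data[[ds$psu_col]]), sep = "||")
  } else {
    stratum <- rep("1", nrow(u))
    psu <- as.character(seq_len(nrow(u)))
  }
  V <- matrix(0, ncol(u), ncol(u))
  for (h in unique(stratum)) {
    in_h <- stratum == h
    z <- rowsum(u[in_h, , drop = FALSE], psu[in_h])
    n_h <- nrow(z)
    if (n_h < 2) {
      fail("stratum '%s' has a single PSU; variance is undefined (no silent collapsing)", h)
    }
    zc <- sweep(z, 2, colMeans(z))
    V <- V + (n_h / (n_h - 1)) * crossprod(zc)
  }
  V
}

#' Design-based standard error of a weighted proportion
#'
#' Taylor linearization under the with-replacement first-stage
#' (ultimate-cluster) approximation: scores `w_i (y_i - p_hat)` are totalled
#' per PSU, and the variance is the stratum-summed scaled between-PSU
#' variance of those totals divided by the squared weight total. For the
#' opt-in kind, each respondent is its own sampling unit in a single stratum.
#'
#' @inheritParams weighted_proportion
#' @return the standard error (nonnegative scalar).
#' @export
design_se <- function(ds, indicator) {
  stopifnot(inherits(ds, "survey_dataset"))
  y <- resolve_indicator(ds, indicator)
  w <- ds_weights(ds)
  p <- sum(w * y) / sum(w)
  u <- w * (y - p)
  V <- ultimate_cluster_var(ds, u)
  sqrt(as.numeric(V) / sum(w)^2)
}

#' Confidence interval for a proportion (logit-transformed)
#'
#' Normal interval for the log-odds with the delta-method standard error
#' `se / (p (1 - p))`, back-transformed to the probability scale. Prevalences
#' near zero make symmetric Wald intervals invalid (they can cross 0); the
#' logit interval respects `[0, 1]` by construction. Degenerate estimates
#' (`p_hat` of exactly 0 or 1, or `se = 0`) collapse to a point interval and
#' are flagged.
#'
#' @param p_hat estimated proportion.
#' @param se design-based standard error.
#' @param level confidence level in (0, 1).
#' @return list with `ci_low`, `ci_high`, `method`, `degenerate`.
#' @export
proportion_ci <- function(p_hat, se, level = 0.95) {
  stopifnot(p_hat >= 0, p_hat <= 1, se >= 0)
  if (level <= 0 || level >= 1) fail("confidence level must lie in (0,1)")
  if (p_hat %in% c(0, 1)) {
    warning("degenerate proportion estimate; returning a point interval")
    return(list(ci_low = p_hat, ci_high = p_hat, method = "logit",
                degenerate = TRUE))
  }
  if (se == 0) {
    return(list(ci_low = p_hat, ci_high = p_hat, method = "logit",
                degenerate = FALSE))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  l <- logit(p_hat)
  se_l <- se / (p_hat * (1 - p_hat))
  list(ci_low = inv_logit(l - z * se_l), ci_high = inv_logit(l + z * se_l),
       method = "logit", degenerate = FALSE)
}

#' Prevalence estimate for one outcome and recency window
#'
#' @inheritParams weighted_proportion
#' @param outcome,recency see [outcome_indicator()].
#' @param level confidence level.
#' @param survey label recorded in the output row.
#' @return one-row data.frame: outcome, recency, survey, p_hat, se, ci_low,
#'   ci_high, n_unweighted, weighted_total, ci_method.
#' @export
svy_prevalence <- function(ds, outcome, recency, level = 0.95,
                           survey = ds$kind) {
  ind <- function(d) outcome_indicator(d, outcome, recency)
  wp <- weighted_proportion(ds, ind)
  se <- design_se(ds, ind)
  ci <- proportion_ci(wp$p_hat, se, level)
  data.frame(outcome = outcome, recency = recency, survey = survey,
             p_hat = wp$p_hat, se = se,
             ci_low = ci$ci_low, ci_high = ci$ci_high,
             n_unweighted = wp$n_unweighted,
             weighted_total = wp$weighted_total,
             ci_method = ci$method, stringsAsFactors = FALSE)
}

#' Prevalence table across outcomes and recency windows
#'
#' One row per outcome x recency, mirroring the per-survey columns of a
#' prevalence comparison table.
#'
#' @inheritParams svy_prevalence
#' @param outcomes,recencies character vectors to cross.
#' @return data.frame of [svy_prevalence()] rows.
#' @export
estimate_prevalences <- function(ds, outcomes = c("heroin", "imf", "either"),
                                 recencies = c("past_year", "past_month",
                                               "months_2_12"),
                                 level = 0.95, survey = ds$kind) {
  rows <- lapply(outcomes, function(oc) {
    do.call(rbind, lapply(recencies, function(rc) {
      svy_prevalence(ds, oc, rc, level = level, survey = survey)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
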