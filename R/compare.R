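# Cross-survey bootstrap comparison. The two surveys' designs differ too much
# to pool, so each is resampled with replacement (PSUs within strata for the
# clustered design, respondents for the panel), the weighted estimate is
# recomputed on every replicate, and the replicate differences give a
# bootstrap-mean point difference with percentile and Bonferroni-corrected
# percentile intervals.

#' Bonferroni-corrected significance level
#'
#' For m simultaneous comparisons at family-wise level alpha, the per-
#' comparison level is alpha/m and intervals are constructed at
#' `100 * (1 - alpha/m)` percent. `alpha_c` is exact; `alpha_c_4dp`
#' truncates to 4 decimals (rounding a significance level down is the
#' conservative display convention).
#'
#' @param alpha family-wise significance level in (0, 1).
#' @param m number of comparisons, at least 1.
#' @return list with `alpha_c`, `alpha_c_4dp`, `ci_level_percent`
#'   (2 decimals).
#' @export
#' @examples
#' bonferroni_alpha(0.05, 43)  # 99.88% corrected intervals
bonferroni_alpha <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    fail("alpha must lie in (0,1)")
  }
  if (!is.numeric(m) || m < 1) fail("m must be a positive comparison count")
  alpha_c <- alpha / m
  list(alpha_c = alpha_c,
       alpha_c_4dp = trunc(alpha_c * 1e4) / 1e4,
       ci_level_percent = round(100 * (1 - alpha_c), 2))
}

# Resampling index protocol (documented and frozen; the oracle tests
# re-execute it independently):
#   set.seed(<child seed>) then
#   - respondent unit: sample.int(n, n, replace = TRUE)
#   - psu unit: for each stratum in sorted order, draw n_h PSU labels with
#     replacement from the stratum's sorted unique labels; a PSU drawn k
#     times contributes k weight-preserving copies of all its rows (rows in
#     original order within each drawn PSU).
resample_indices <- function(ds, seed, unit, frame = NULL) {
  set.seed(seed)
  n <- nrow(ds$data)
  if (unit == "respondent") return(sample.int(n, n, replace = TRUE))
  if (is.null(frame)) frame <- psu_frame(ds)
  pieces <- vector("list", length(frame))
  for (i in seq_along(frame)) {
    st <- frame[[i]]
    draw <- sample(st$labs, length(st$labs), replace = TRUE)
    pieces[[i]] <- st$members[draw]
  }
  pieces <- unlist(pieces, recursive = FALSE, use.names = FALSE)
  idx <- unlist(pieces, use.names = FALSE)
  attr(idx, "draw_id") <- rep.int(seq_along(pieces), lengths(pieces))
  idx
}

# Pre-split row indices by stratum (sorted) and PSU label (sorted), so a
# replicate draw is a pure table lookup.
psu_frame <- function(ds) {
  stratum <- as.character(ds$data[[ds$stratum_col]])
  psu <- as.character(ds$data[[ds$psu_col]])
  lapply(sort(unique(stratum)), function(h) {
    in_h <- which(stratum == h)
    members <- split(in_h, psu[in_h])
    labs <- sort(names(members))
    list(labs = labs, members = members[labs])
  })
}

default_resample_unit <- function(ds) {
  if (ds$kind == "probability_clustered") "psu" else "respondent"
}

#' Resample a survey for one bootstrap replicate
#'
#' Probability-clustered surveys resample first-stage clusters: within each
#' stratum, n_h PSUs are drawn with replacement from the n_h sampled PSUs
#' (respecting the with-replacement assumption of the variance estimator);
#' opt-in panels resample respondents. Weights are carried into the replicate
#' unmodified. Identical seed gives an identical replicate.
#'
#' @param ds a [survey_dataset()].
#' @param seed integer seed for this replicate.
#' @param unit `"psu"` or `"respondent"`; defaults to the design-appropriate
#'   unit (`psu` for probability_clustered, `respondent` for optin_panel).
#' @return a replicate [survey_dataset()] with all original columns.
#' @export
resample_survey <- function(ds, seed, unit = default_resample_unit(ds),
                            frame = NULL) {
  stopifnot(inherits(ds, "survey_dataset"))
  unit <- match.arg(unit, c("psu", "respondent"))
  if (unit == "psu" && ds$kind != "probability_clustered") {
    fail("PSU resampling requires a probability_clustered design")
  }
  idx <- resample_indices(ds, seed, unit, frame)
  d <- ds$data[idx, , drop = FALSE]
  rownames(d) <- NULL
  out <- ds
  out$data <- d
  # replicate PSU copies are distinct resampled clusters: relabel by draw so
  # a PSU drawn twice is two clusters, as the with-replacement bootstrap assumes
  if (unit == "psu") {
    out$data[[ds$psu_col]] <- paste0(d[[ds$psu_col]], ".",
                                     attr(idx, "draw_id"))
  }
  out$meta$replicate_seed <- seed
  out
}

#' Bootstrap replicate differences between two surveys
#'
#' For replicate b, each survey is independently resampled with child seeds
#' `child_seed(seed, b, "A")` / `child_seed(seed, b, "B")`, the estimator is
#' recomputed on each replicate, and the difference (survey B minus survey A)
#' is recorded. The estimator may return a named vector (one element per
#' quantity). Replicates on which the estimator fails are excluded and
#' counted; more than 5% exclusions is an error.
#'
#' @param survey_a,survey_b [survey_dataset()]s harmonized to the same
#'   dictionary.
#' @param estimator function(survey_dataset) -> numeric (scalar or named
#'   vector), e.g. a weighted prevalence.
#' @param B replicate count (the reference analysis uses 2000).
#' @param seed master seed for the replicate streams.
#' @param unit_a,unit_b resampling units, defaulting per design kind.
#' @return B x k matrix of replicate differences (excluded replicates as NA
#'   rows), with attributes `n_excluded` and `units`.
#' @export
bootstrap_differences <- function(survey_a, survey_b, estimator, B = 2000,
                                  seed,
                                  unit_a = default_resample_unit(survey_a),
                                  unit_b = default_resample_unit(survey_b)) {
  stopifnot(B >= 1)
  frame_a <- if (unit_a == "psu") psu_frame(survey_a) else NULL
  frame_b <- if (unit_b == "psu") psu_frame(survey_b) else NULL
  est0 <- estimator(survey_a)
  k <- length(est0)
  out <- matrix(NA_real_, nrow = B, ncol = k)
  colnames(out) <- names(est0)
  excl <- 0L
  for (b in seq_len(B)) {
    res <- tryCatch({
      ra <- resample_survey(survey_a, child_seed(seed, b, "A"), unit_a,
                            frame = frame_a)
      rb <- resample_survey(survey_b, child_seed(seed, b, "B"), unit_b,
                            frame = frame_b)
      as.numeric(estimator(rb)) - as.numeric(estimator(ra))
    }, error = function(e) NULL)
    if (is.null(res)) excl <- excl + 1L else out[b, ] <- res
  }
  if (excl / B > 0.05) {
    fail("%d of %d bootstrap replicates failed (> 5%%); refusing to summarize",
         excl, B)
  }
  attr(out, "n_excluded") <- excl
  attr(out, "units") <- c(A = unit_a, B = unit_b)
  out
}

# Fast replicate-difference engine for weighted-proportion quantities:
# identical to bootstrap_differences(estimator = weighted proportions) by
# construction, because it consumes the same resample_indices streams.
bootstrap_proportion_differences <- function(survey_a, survey_b, quantities,
                                             B, seed,
                                             unit_a = default_resample_unit(survey_a),
                                             unit_b = default_resample_unit(survey_b)) {
  Ya <- vapply(quantities, function(f) resolve_indicator(survey_a, f),
               logical(nrow(survey_a$data)))
  Yb <- vapply(quantities, function(f) resolve_indicator(survey_b, f),
               logical(nrow(survey_b$data)))
  wa <- ds_weights(survey_a); wb <- ds_weights(survey_b)
  frame_a <- if (unit_a == "psu") psu_frame(survey_a) else NULL
  frame_b <- if (unit_b == "psu") psu_frame(survey_b) else NULL
  out <- matrix(NA_real_, nrow = B, ncol = length(quantities))
  colnames(out) <- names(quantities)
  for (b in seq_len(B)) {
    ia <- resample_indices(survey_a, child_seed(seed, b, "A"), unit_a, frame_a)
    ib <- resample_indices(survey_b, child_seed(seed, b, "B"), unit_b, frame_b)
    pa <- colSums(wa[ia] * Ya[ia, , drop = FALSE]) / sum(wa[ia])
    pb <- colSums(wb[ib] * Yb[ib, , drop = FALSE]) / sum(wb[ib])
    out[b, ] <- pb - pa
  }
  attr(out, "n_excluded") <- 0L
  attr(out, "units") <- c(A = unit_a, B = unit_b)
  out
}

#' Summarize a replicate difference distribution
#'
#' The point difference is the arithmetic mean of the replicate differences;
#' the interval is the percentile interval (empirical quantiles at
#' `alpha/2` and `1 - alpha/2`) and the corrected interval the percentile
#' interval at the Bonferroni level `alpha/m`. Quantile rule: linearly
#' interpolated inverse empirical CDF (R quantile type 4), fixed; its tails
#' reach the extreme order statistics sooner than the default type-7 rule,
#' which matters at the near-unity levels Bonferroni correction produces.
#'
#' @param diffs numeric vector of replicate differences (NAs, from excluded
#'   replicates, are dropped).
#' @param alpha family-wise level.
#' @param m number of comparisons in the family.
#' @param quantity label for the output row.
#' @param seed seed recorded for provenance.
#' @return one-row data.frame: quantity, diff_point, ci_low, ci_high,
#'   cci_low, cci_high, B (replicates used), n_excluded, alpha, m, alpha_c,
#'   seed.
#' @export
summarize_difference <- function(diffs, alpha = 0.05, m = 1,
                                 quantity = "difference", seed = NA_integer_) {
  n_excluded <- sum(is.na(diffs))
  diffs <- diffs[!is.na(diffs)]
  if (length(diffs) == 0) fail("no replicate differences to summarize")
  bc <- bonferroni_alpha(alpha, m)
  q <- function(a) unname(stats::quantile(diffs, c(a / 2, 1 - a / 2), type = 4))
  ci <- q(alpha)
  cci <- q(bc$alpha_c)
  point <- mean(diffs)
  stopifnot(cci[1] <= ci[1] + 1e-12, cci[2] >= ci[2] - 1e-12,
            point >= min(diffs) - 1e-12, point <= max(diffs) + 1e-12)
  data.frame(quantity = quantity, diff_point = point,
             ci_low = ci[1], ci_high = ci[2],
             cci_low = cci[1], cci_high = cci[2],
             B = length(diffs), n_excluded = n_excluded,
             alpha = alpha, m = m, alpha_c = bc$alpha_c,
             seed = seed, stringsAsFactors = FALSE)
}

#' Compare two surveys over a family of weighted-proportion quantities
#'
#' Runs the replicate bootstrap over all quantities at once (the same
#' replicate resamples serve every quantity, as when a survey is resampled
#' whole), and reports, per quantity: the per-survey point estimates with
#' design-based CIs, the plain survey-B-minus-survey-A difference of the
#' original point estimates, and the bootstrap summary with percentile CI
#' and Bonferroni-corrected CI. All prevalences and differences are on the
#' percentage scale.
#'
#' @param survey_a,survey_b harmonized [survey_dataset()]s; the difference is
#'   signed as B minus A.
#' @param quantities named list of indicator functions
#'   (`function(data) -> logical`); defaults to the outcome x recency grid.
#' @param B bootstrap replicates.
#' @param alpha family-wise level.
#' @param m comparison-family size (defaults to `length(quantities)`; may be
#'   set larger when the family includes comparisons made elsewhere).
#' @param seed master seed.
#' @param level per-survey CI level.
#' @param unit_a,unit_b resampling units (see [resample_survey()]).
#' @return data.frame, one row per quantity; a manifest of every decision
#'   switch is attached as attribute `"manifest"`.
#' @export
compare_surveys <- function(survey_a, survey_b,
                            quantities = default_quantities(),
                            B = 2000, alpha = 0.05, m = length(quantities),
                            seed, level = 0.95,
                            unit_a = default_resample_unit(survey_a),
                            unit_b = default_resample_unit(survey_b)) {
  if (m < length(quantities)) {
    fail("comparison family size m (%d) smaller than the number of quantities (%d)",
         m, length(quantities))
  }
  diffs <- bootstrap_proportion_differences(survey_a, survey_b, quantities,
                                            B = B, seed = seed,
                                            unit_a = unit_a, unit_b = unit_b)
  rows <- lapply(names(quantities), function(qn) {
    f <- quantities[[qn]]
    wa <- weighted_proportion(survey_a, f)
    wb <- weighted_proportion(survey_b, f)
    sa <- design_se(survey_a, f); sb <- design_se(survey_b, f)
    ca <- proportion_ci(wa$p_hat, sa, level)
    cb <- proportion_ci(wb$p_hat, sb, level)
    s <- summarize_difference(100 * diffs[, qn], alpha = alpha, m = m,
                              quantity = qn, seed = seed)
    cbind(data.frame(quantity = qn,
                     est_a = 100 * wa$p_hat,
                     ci_low_a = 100 * ca$ci_low, ci_high_a = 100 * ca$ci_high,
                     est_b = 100 * wb$p_hat,
                     ci_low_b = 100 * cb$ci_low, ci_high_b = 100 * cb$ci_high,
                     diff_plain = 100 * (wb$p_hat - wa$p_hat),
                     stringsAsFactors = FALSE),
          s[, setdiff(names(s), "quantity")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "manifest") <- list(
    B = B, alpha = alpha, m = m, alpha_c = alpha / m, seed = seed,
    resample_unit = list(A = unit_a, B = unit_b),
    reraking_per_replicate = FALSE,
    quantile_rule = "type 4 (linearly interpolated inverse empirical CDF)",
    n_excluded = attr(diffs, "n_excluded"),
    sign_convention = "survey B minus survey A",
    scale = "percentage points")
  out
}

#' Default comparison family: outcome x recency prevalences
#' @return named list of indicator functions over harmonized records.
#' @export
default_quantities <- function() {
  grid <- expand.grid(outcome = c("heroin", "imf", "either"),
                      recency = c("past_year", "past_month", "months_2_12"),
                      stringsAsFactors = FALSE)
  qs <- lapply(seq_len(nrow(grid)), function(i) {
    oc <- grid$outcome[i]; rc <- grid$recency[i]
    local({
      oc <- oc; rc <- rc
      function(d) outcome_indicator(d, oc, rc)
    })
  })
  names(qs) <- paste(grid$outcome, grid$recency, sep = ".")
  qs
}
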