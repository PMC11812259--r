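# Published 2022 prevalence table (weighted percentages with 95% CIs from
# the two national surveys) shipped as a plain-text input, and the printed
# difference identity: panel minus probability-survey prevalence.

#' Published 2022 prevalence estimates
#'
#' Weighted past-year / past-month / 2-12-month prevalence of heroin, IMF and
#' either-use as published for the 2022 probability household survey and the
#' 2022 opt-in panel, on the percentage scale.
#'
#' @return data.frame: outcome, recency, survey
#'   (`probability` | `panel`), estimate_pct, ci_low_pct, ci_high_pct.
#' @export
published_prevalence <- function() {
  utils::read.csv(system.file("extdata", "published_prevalence_2022.csv",
                              package = "dualsurvey"),
                  stringsAsFactors = FALSE)
}

#' Panel-minus-probability differences of published point estimates
#'
#' Applies the published subtraction convention (panel prevalence minus
#' probability-survey prevalence) to the shipped point estimates, rounding to
#' the published 2-decimal display.
#'
#' @param published table from [published_prevalence()].
#' @return data.frame: outcome, recency, est_probability, est_panel,
#'   difference_pct.
#' @export
published_differences <- function(published = published_prevalence()) {
  wide <- merge(
    published[published$survey == "probability",
              c("outcome", "recency", "estimate_pct")],
    published[published$survey == "panel",
              c("outcome", "recency", "estimate_pct")],
    by = c("outcome", "recency"), suffixes = c("_probability", "_panel"))
  wide$difference_pct <- round(
    wide$estimate_pct_panel - wide$estimate_pct_probability, 2)
  names(wide)[3:4] <- c("est_probability", "est_panel")
  wide[order(wide$outcome, wide$recency), ]
}
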