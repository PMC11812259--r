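Package: dualsurvey
Title: Cross-Survey Prevalence Comparison for Probability and Opt-In Panel Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design-based estimation and cross-survey comparison of substance-use
    prevalence between a stratified two-stage probability household survey and an
    opt-in online panel. Implements weighted prevalence estimation with Taylor
    ultimate-cluster variance, logit-transformed confidence intervals, a
    replicate-resampling bootstrap difference estimator with Bonferroni-corrected
    percentile intervals, raking (iterative proportional fitting) calibration for
    nonprobability panels, survey-weighted logistic regression with linearized
    sandwich covariance, generalized variance-inflation screening, and
    delta-method average marginal effects. Ships a synthetic dual-survey
    generator with known population truth so every estimator is testable
    end-to-end without restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
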