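#!/usr/bin/env Rscript
# Stage 2: per-survey design-based prevalence estimates.
#
# Weighted percentages with Taylor ultimate-cluster SEs and logit-transformed
# 95% CIs for heroin, IMF and either-use by recency window, one row per
# outcome x recency x survey (the per-survey columns of a Table-2-style
# comparison). Requires the datasets written by 01_simulate.R.

library(dualsurvey)

ds_a <- read_survey_dataset("results/data/survey_probability")
ds_b <- read_survey_dataset("results/data/survey_panel")

est <- rbind(estimate_prevalences(ds_a, survey = "probability"),
             estimate_prevalences(ds_b, survey = "panel"))
est_pct <- transform(est, p_hat = 100 * p_hat, se = 100 * se,
                     ci_low = 100 * ci_low, ci_high = 100 * ci_high)
cat("weighted prevalence (%) with 95% CI:\n")
print(est_pct[est_pct$recency == "past_year",
              c("outcome", "survey", "p_hat", "ci_low", "ci_high",
                "n_unweighted")], digits = 3)

truth <- read.csv("results/data/truth_realized.csv")
cat("\nrealized population truth (%):\n")
print(transform(truth, prevalence = 100 * prevalence), digits = 3)

write.csv(est_pct, "results/prevalence_estimates.csv", row.names = FALSE)
cat("\nwrote results/prevalence_estimates.csv\n")
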