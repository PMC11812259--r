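#!/usr/bin/env Rscript
# Stage 1: generate the synthetic population and draw the two surveys.
#
# The default configuration emulates the study conditions of a national
# dual-survey comparison: a latent adult population of 200,000 with either-use
# (heroin or illicitly manufactured fentanyl) prevalence near 0.5%, a
# stratified two-stage probability household sample with employment-dependent
# nonresponse, and an opt-in web panel whose self-selection over-recruits
# college graduates and people who use stimulants/benzodiazepines, raked back
# to demographic margins. Writes the datasets (CSV + JSON design sidecars)
# and the realized population truth under results/data/.

library(dualsurvey)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 42L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

truth <- population_truth()  # pop 200,000, documented illustrative defaults
gen <- generate_population(truth, seed)
cat("population generated:", truth$pop_size, "persons\n")
print(gen$realized_prevalence)

ds_a <- draw_probability_sample(gen$population, default_probability_design(),
                                seed = child_seed(seed, "survey_a"))
ds_b <- draw_optin_sample(gen$population, default_optin_design(),
                          seed = child_seed(seed, "survey_b"))
cat("\nprobability survey: ", nrow(ds_a$data), " respondents, weighted total ",
    round(sum(ds_a$data$weight)), "\n", sep = "")
cat("opt-in panel:       ", nrow(ds_b$data), " respondents, weighted total ",
    round(sum(ds_b$data$weight)), " (raked in ",
    ds_b$meta$raking$iterations, " IPF passes)\n", sep = "")

write_survey_dataset(harmonize_survey(ds_a), "results/data/survey_probability")
write_survey_dataset(harmonize_survey(ds_b), "results/data/survey_panel")
write.csv(gen$realized_prevalence, "results/data/truth_realized.csv",
          row.names = FALSE)
cat("\nwrote results/data/{survey_probability,survey_panel}.{csv,json}\n")
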