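# Fixtures built in code: tiny survey datasets and reduced population truths
# used across the module tests.

# Opt-in style dataset: respondents are their own sampling units.
toy_panel <- function(y, w = rep(1, length(y)), extra = NULL) {
  d <- data.frame(respondent_id = seq_along(y), y = y, weight = w)
  if (!is.null(extra)) d <- cbind(d, extra)
  survey_dataset(d, kind = "optin_panel")
}

# Clustered dataset from explicit stratum / psu / weight / y vectors.
toy_clustered <- function(stratum, psu, y, w = rep(1, length(y))) {
  survey_dataset(
    data.frame(respondent_id = seq_along(y), stratum = stratum, psu = psu,
               y = y, weight = w),
    kind = "probability_clustered",
    stratum_col = "stratum", psu_col = "psu")
}

# Reduced population truth: three covariates, small enough for exhaustive
# enumeration oracles.
small_truth <- function(pop_size = 50000,
                        intercept = -5, stim = 2, female = -0.5) {
  population_truth(
    pop_size = pop_size,
    covariate_spec = list(
      sex = c(male = 0.48, female = 0.52),
      stimulant = c(no = 0.95, yes = 0.05),
      employment = c(none = 0.4, past_week = 0.6)),
    outcome_coefficients = list(
      heroin = c("(Intercept)" = intercept, "stimulant" = stim,
                 "sex=female" = female),
      imf = c("(Intercept)" = intercept + 0.2, "stimulant" = stim)),
    recency_split = c(heroin = 0.6, imf = 0.4),
    associations = list(),
    cigarette_blank_rate = 0)
}

# A raw-instrument data.frame that harmonize_survey() accepts, with n rows.
raw_survey_frame <- function(n, seed = 1) {
  set.seed(seed)
  py_h <- runif(n) < 0.3
  pm_h <- py_h & runif(n) < 0.5
  py_i <- runif(n) < 0.2
  pm_i <- py_i & runif(n) < 0.5
  data.frame(
    respondent_id = seq_len(n),
    heroin_past_year = py_h, heroin_past_month = pm_h,
    imf_past_year = py_i, imf_past_month = pm_i,
    drinks_per_week = runif(n, 0, 30),
    sex = sample(c("male", "female"), n, TRUE),
    race = sample(c("non-Hispanic White", "non-Hispanic Black", "Hispanic",
                    "Asian", "Other"), n, TRUE),
    cigarette = sample(c("every day", "some days", "not at all", NA), n, TRUE),
    weight = runif(n, 0.5, 3),
    stringsAsFactors = FALSE)
}
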