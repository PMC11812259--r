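test_that("population generation is seed-deterministic and validates inputs", {
  tr <- small_truth(pop_size = 2000)
  g1 <- generate_population(tr, 42)
  g2 <- generate_population(tr, 42)
  expect_identical(g1$population, g2$population)
  g3 <- generate_population(tr, 43)
  expect_false(identical(g1$population, g3$population))
  # margins must sum to one; coefficients must be finite
  expect_error(population_truth(covariate_spec = list(sex = c(male = 0.6, female = 0.5))),
               "sum to")
  bad <- small_truth()
  expect_error(population_truth(
    covariate_spec = bad$covariate_spec,
    outcome_coefficients = list(heroin = c("(Intercept)" = Inf),
                                imf = c("(Intercept)" = -5))),
    "non-finite")
})

test_that("degenerate and symmetric outcome models give the expected prevalence", {
  # intercept -50: probability ~ 0
  tr0 <- small_truth(pop_size = 10000, intercept = -50, stim = 0, female = 0)
  g0 <- generate_population(tr0, 1)
  expect_equal(sum(g0$population$heroin_past_year), 0)
  # intercept 0, no effects: prevalence within 3 Monte-Carlo SEs of 0.5
  trh <- small_truth(pop_size = 200000, intercept = 0, stim = 0, female = 0)
  gh <- generate_population(trh, 2)
  p <- mean(gh$population$heroin_past_year)
  mc_se <- sqrt(0.5 * 0.5 / 200000)
  expect_lt(abs(p - 0.5), 3 * mc_se)
})

test_that("realized prevalence matches brute-force enumeration of the model", {
  # exhaustive expectation over all covariate cells is the oracle
  tr <- small_truth(pop_size = 500000, intercept = -4.8, stim = 2.2,
                    female = -0.4)
  implied <- model_implied_prevalence(tr, "either")
  g <- generate_population(tr, 9)
  realized <- g$realized_prevalence
  p_real <- realized$prevalence[realized$outcome == "either" &
                                  realized$recency == "past_year"]
  mc_se <- sqrt(implied * (1 - implied) / tr$pop_size)
  expect_lt(abs(p_real - implied), 3 * mc_se)
  # realized table is an exact exhaustive count over the population
  pop <- g$population
  expect_equal(p_real, mean(pop$heroin_past_year | pop$imf_past_year))
  # either >= max(heroin, imf) and <= heroin + imf
  by_oc <- function(oc) realized$prevalence[realized$outcome == oc &
                                              realized$recency == "past_year"]
  expect_gte(by_oc("either"), max(by_oc("heroin"), by_oc("imf")))
  expect_lte(by_oc("either"), by_oc("heroin") + by_oc("imf"))
})

test_that("pairwise association tilt reproduces the requested odds ratio", {
  spec <- list(stimulant = c(no = 0.9, yes = 0.1),
               benzodiazepine = c(no = 0.85, yes = 0.15))
  tr <- population_truth(
    pop_size = 200000, covariate_spec = spec,
    outcome_coefficients = list(heroin = c("(Intercept)" = -5),
                                imf = c("(Intercept)" = -5)),
    recency_split = c(heroin = 0.5, imf = 0.5),
    associations = list(list(a = "stimulant", b = "benzodiazepine",
                             log_or = 1.2)),
    cigarette_blank_rate = 0)
  pop <- generate_population(tr, 5)$population
  tab <- table(pop$stimulant, pop$benzodiazepine)
  log_or_hat <- log(tab["yes", "yes"] * tab["no", "no"] /
                      (tab["yes", "no"] * tab["no", "yes"]))
  se <- sqrt(sum(1 / tab))
  expect_lt(abs(log_or_hat - 1.2), 3 * se)
  # margins preserved
  expect_lt(abs(mean(pop$benzodiazepine == "yes") - 0.15),
            3 * sqrt(0.15 * 0.85 / 200000))
})

test_that("census design is the identity: unit weights, exact population prevalence", {
  tr <- small_truth(pop_size = 1200, intercept = -2, stim = 1, female = 0)
  pop <- generate_population(tr, 3)$population
  census <- survey_design_spec("probability_clustered", n_strata = 2,
                               psus_per_stratum = 2,
                               sample_psus_per_stratum = 2,
                               respondents_per_psu = 1200)
  ds <- draw_probability_sample(pop, census, seed = 10)
  expect_equal(nrow(ds$data), 1200)
  expect_true(all(ds$data$weight == 1))
  wp <- weighted_proportion(ds, function(d) d$heroin_past_year)
  expect_identical(wp$p_hat, mean(pop$heroin_past_year))
})

test_that("equal-probability two-stage design is self-weighting", {
  tr <- small_truth(pop_size = 800, intercept = -2, stim = 0, female = 0)
  pop <- generate_population(tr, 4)$population
  # 2 strata x 2 PSUs, all PSUs sampled, 50 per PSU: balanced partition gives
  # 200-person PSUs, 4 x 50 = 200 respondents, every weight 800 / 200
  des <- survey_design_spec("probability_clustered", n_strata = 2,
                            psus_per_stratum = 2, sample_psus_per_stratum = 2,
                            respondents_per_psu = 50)
  ds <- draw_probability_sample(pop, des, seed = 11)
  expect_equal(nrow(ds$data), 200)
  expect_true(all(abs(ds$data$weight - 800 / 200) < 1e-12))
})

test_that("nonresponse adjustment equals hand-computed inverse class response rates", {
  # 100-person toy population, census first stage, nonresponse depends on
  # employment: final weights must be base weight x (class sampled mass /
  # class responding mass), so employed respondents (lower propensity)
  # carry the larger weights
  tr <- small_truth(pop_size = 100, intercept = -2, stim = 0, female = 0)
  pop <- generate_population(tr, 6)$population
  des <- survey_design_spec(
    "probability_clustered", n_strata = 2, psus_per_stratum = 2,
    sample_psus_per_stratum = 2, respondents_per_psu = 100,
    nonresponse_model = c("(Intercept)" = 1.5, "employment=past_week" = -1.5))
  ds <- draw_probability_sample(pop, des, seed = 12)
  d <- ds$data
  # base weights were 1 (census); hand-compute class response rates
  n_emp <- sum(pop$employment == "past_week")
  n_non <- sum(pop$employment == "none")
  r_emp <- sum(d$employment == "past_week") / n_emp
  r_non <- sum(d$employment == "none") / n_non
  expect_equal(unique(d$weight[d$employment == "past_week"]), 1 / r_emp,
               tolerance = 1e-12)
  expect_equal(unique(d$weight[d$employment == "none"]), 1 / r_non,
               tolerance = 1e-12)
  expect_gt(mean(d$weight[d$employment == "past_week"]),
            mean(d$weight[d$employment == "none"]))
  # weight mass is preserved exactly within class (sums to class size)
  expect_equal(sum(d$weight), 100, tolerance = 1e-9)
})

test_that("intercept-only opt-in selection gives a simple random subsample with equal raked weights", {
  tr <- small_truth(pop_size = 20000, intercept = -3, stim = 0, female = 0)
  pop <- generate_population(tr, 7)$population
  des <- survey_design_spec("optin_panel",
                            selection_model = c("(Intercept)" = -2.5),
                            raking_margins = NULL)
  ds <- draw_optin_sample(pop, des, seed = 13)
  n <- nrow(ds$data)
  expect_true(all(abs(ds$data$weight - 20000 / n) < 1e-9))
  expect_null(ds$stratum_col)
  # selection rate close to inverse-logit(-2.5)
  expect_lt(abs(n / 20000 - 1 / (1 + exp(2.5))),
            3 * sqrt(0.076 * 0.924 / 20000))
})

test_that("selection skew is corrected on raked margins but visible unweighted", {
  tr <- population_truth(pop_size = 30000)
  pop <- generate_population(tr, 8)$population
  des <- default_optin_design()
  ds <- draw_optin_sample(pop, des, seed = 14)
  d <- ds$data
  pop_share <- mean(pop$education == "college graduate")
  raw_share <- mean(d$education == "college graduate")
  wtd_share <- sum(d$weight * (d$education == "college graduate")) / sum(d$weight)
  expect_gt(raw_share, pop_share)              # panel over-recruits graduates
  expect_lt(abs(wtd_share - pop_share), 1e-6)  # raking restores the margin
  expect_equal(sum(d$weight), 30000, tolerance = 1e-3)
})

test_that("probability-sample weighted prevalence is unbiased over replicate draws", {
  # parameter recovery at desk scale: mean error of the weighted either-use
  # prevalence across replicate dual-survey draws is within 3 MC SEs of 0
  tr <- small_truth(pop_size = 4000, intercept = -3.2, stim = 1.5,
                    female = -0.3)
  pop <- generate_population(tr, 20)$population
  p_true <- mean(pop$heroin_past_year | pop$imf_past_year)
  des <- survey_design_spec("probability_clustered", n_strata = 4,
                            psus_per_stratum = 4, sample_psus_per_stratum = 2,
                            respondents_per_psu = 120)
  errs <- vapply(seq_len(200), function(r) {
    ds <- draw_probability_sample(pop, des, seed = r)
    weighted_proportion(ds, function(d) d$heroin_past_year | d$imf_past_year)$p_hat - p_true
  }, numeric(1))
  expect_lt(abs(mean(errs)), 3 * stats::sd(errs) / sqrt(length(errs)))
})

test_that("survey datasets round-trip through CSV plus JSON sidecar", {
  d <- raw_survey_frame(50, seed = 3)
  d$stratum <- rep(1:2, each = 25)
  d$psu <- rep(1:10, each = 5)
  ds <- survey_dataset(d, kind = "probability_clustered",
                       stratum_col = "stratum", psu_col = "psu", seed = 99)
  stem <- file.path(tempdir(), "roundtrip")
  write_survey_dataset(ds, stem)
  back <- read_survey_dataset(stem)
  expect_equal(back$kind, ds$kind)
  expect_equal(back$data$weight, ds$data$weight)
  expect_equal(back$seed, 99)
  expect_equal(nrow(back$data), 50)
})
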