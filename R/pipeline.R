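# End-to-end orchestration: generate a population, draw both surveys,
# harmonize, estimate per-survey prevalences, bootstrap the cross-survey
# differences, fit per-survey weighted logistic models with AMEs, and write
# the result tables plus a truth-recovery report. Every random draw flows
# from the single config seed through the child-seed scheme, so a rerun with
# the same config reproduces byte-identical outputs.

#' Default probability-survey design for the shipped configuration
#' @return a [survey_design_spec()].
#' @export
default_probability_design <- function() {
  survey_design_spec(
    kind = "probability_clustered",
    n_strata = 8, psus_per_stratum = 6,
    sample_psus_per_stratum = 4, respondents_per_psu = 800,
    nonresponse_model = c("(Intercept)" = 1.4, "employment=past_week" = -0.6))
}

#' Default opt-in panel design for the shipped configuration
#'
#' The selection model over-recruits college graduates, non-Hispanic White
#' respondents and people who use stimulants or benzodiazepines, and
#' under-recruits the employed -- the covariate skews reported for opt-in
#' panels. Raking calibrates age, sex, race, education and income back to the
#' population margins, but the unraked substance-use skew persists, so the
#' panel's weighted prevalence stays above the probability survey's.
#' @return a [survey_design_spec()].
#' @export
default_optin_design <- function() {
  survey_design_spec(
    kind = "optin_panel",
    selection_model = c("(Intercept)" = -3.05,
                        "education=college graduate" = 0.50,
                        "race=non-Hispanic White" = 0.30,
                        "employment=past_week" = -0.40,
                        "cigarette=not at all" = -0.35,
                        "stimulant" = 1.50, "benzodiazepine" = 1.00),
    raking_margins = c("age_group", "sex", "race", "education", "income"))
}

#' Default regression formula for the shipped configuration
#' @return a formula for past-year either-use on the analytic covariates.
#' @export
default_regression_formula <- function() {
  either_py ~ age_group + sex + income + employment + insurance +
    cigarette3 + cannabis + stimulant + benzodiazepine + moud +
    hospitalization
}

#' Assemble and validate a pipeline run configuration
#'
#' @param seed master integer seed; every stage derives child seeds from it.
#' @param truth a [population_truth()].
#' @param design_a probability-kind [survey_design_spec()] (survey A).
#' @param design_b optin-kind [survey_design_spec()] (survey B).
#' @param quantities named list of comparison indicator functions (the
#'   comparison family).
#' @param m Bonferroni family size; must equal `length(quantities)`.
#' @param alpha family-wise level.
#' @param B bootstrap replicates (reference analysis: 2000).
#' @param formula regression formula (outcome `either_py` is created from the
#'   harmonized recency).
#' @param level per-survey CI level.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(seed,
                       truth = population_truth(),
                       design_a = default_probability_design(),
                       design_b = default_optin_design(),
                       quantities = default_quantities(),
                       m = length(quantities),
                       alpha = 0.05, B = 2000,
                       formula = default_regression_formula(),
                       level = 0.95) {
  stopifnot(inherits(truth, "population_truth"),
            inherits(design_a, "survey_design_spec"),
            inherits(design_b, "survey_design_spec"))
  if (design_a$kind != "probability_clustered" ||
      design_b$kind != "optin_panel") {
    fail("survey A must be probability_clustered and survey B optin_panel")
  }
  if (m != length(quantities)) {
    fail("m (%d) must equal the comparison-family size (%d)",
         m, length(quantities))
  }
  if (B < 1) fail("B must be at least 1")
  structure(list(seed = as.integer(seed), truth = truth,
                 design_a = design_a, design_b = design_b,
                 quantities = quantities, m = m, alpha = alpha, B = B,
                 formula = formula, level = level),
            class = "run_config")
}

add_analysis_outcomes <- function(ds) {
  ds$data$either_py <- outcome_indicator(ds$data, "either", "past_year")
  ds
}

#' Run the full dual-survey pipeline
#'
#' Stages: generate population -> draw probability sample (survey A) and
#' opt-in panel (survey B) -> harmonize -> per-survey prevalence table ->
#' bootstrap difference table -> per-survey weighted logistic fits with AMEs
#' -> truth-recovery report. All tables are written to `out_dir` as CSV with
#' a JSON manifest; a failed stage aborts with the stage name and removes the
#' partial outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed); NULL skips writing.
#' @return invisibly, a list with population truth, the two datasets, and the
#'   result tables (`estimates`, `differences`, `regression`, `ame`,
#'   `recovery`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  written <- character(0)
  stage <- "setup"
  result <- tryCatch({
    stage <- "generate_population"
    gen <- generate_population(config$truth, config$seed)
    stage <- "draw_surveys"
    ds_a <- draw_probability_sample(gen$population, config$design_a,
                                    seed = child_seed(config$seed, "survey_a"))
    ds_b <- draw_optin_sample(gen$population, config$design_b,
                              seed = child_seed(config$seed, "survey_b"))
    stage <- "harmonize"
    ds_a <- add_analysis_outcomes(harmonize_survey(ds_a))
    ds_b <- add_analysis_outcomes(harmonize_survey(ds_b))
    stage <- "estimate"
    est_a <- estimate_prevalences(ds_a, level = config$level, survey = "A")
    est_b <- estimate_prevalences(ds_b, level = config$level, survey = "B")
    estimates <- rbind(est_a, est_b)
    stage <- "compare"
    differences <- compare_surveys(
      ds_a, ds_b, quantities = config$quantities, B = config$B,
      alpha = config$alpha, m = config$m,
      seed = child_seed(config$seed, "bootstrap"), level = config$level)
    stage <- "regression"
    fit_a <- fit_weighted_logit(ds_a, config$formula)
    fit_b <- fit_weighted_logit(ds_b, config$formula)
    regression <- rbind(cbind(survey = "A", fit_a$aor),
                        cbind(survey = "B", fit_b$aor))
    vif <- rbind(cbind(survey = "A", fit_a$vif),
                 cbind(survey = "B", fit_b$vif))
    stage <- "ame"
    ame <- rbind(cbind(survey = "A", average_marginal_effects(fit_a)),
                 cbind(survey = "B", average_marginal_effects(fit_b)))
    stage <- "recovery"
    recovery <- recovery_table(estimates, differences,
                               gen$realized_prevalence)
    manifest <- list(
      seed = config$seed,
      pop_size = config$truth$pop_size,
      B = config$B, m = config$m, alpha = config$alpha,
      alpha_c = config$alpha / config$m,
      level = config$level,
      formula = deparse(config$formula),
      reference_levels = as.list(fit_a$reference_levels),
      compare = attr(differences, "manifest"),
      raking = ds_b$meta$raking[c("iterations", "converged", "margins")],
      n_respondents = c(A = nrow(ds_a$data), B = nrow(ds_b$data)),
      software = list(package = "dualsurvey",
                      r_version = paste(R.version$major, R.version$minor,
                                        sep = ".")),
      schema_version = "1")
    list(truth = config$truth, realized_prevalence = gen$realized_prevalence,
         survey_a = ds_a, survey_b = ds_b, estimates = estimates,
         differences = differences, regression = regression, vif = vif,
         ame = ame, fit_a = fit_a, fit_b = fit_b, recovery = recovery,
         manifest = manifest)
  }, error = function(e) {
    fail("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  if (!is.null(out_dir)) {
    tryCatch({
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      wrt <- function(obj, name) {
        f <- file.path(out_dir, name)
        utils::write.csv(obj, f, row.names = FALSE)
        written <<- c(written, f)
      }
      wrt(result$estimates, "estimates.csv")
      wrt(result$differences, "differences.csv")
      wrt(result$regression, "regression.csv")
      wrt(result$vif, "vif.csv")
      wrt(result$ame, "ame.csv")
      wrt(result$recovery, "recovery.csv")
      wrt(result$realized_prevalence, "truth_realized.csv")
      jsonlite::write_json(result$manifest,
                           file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      written <<- c(written, file.path(out_dir, "manifest.json"))
    }, error = function(e) {
      for (f in written) unlink(f)  # no partial run directories
      fail("pipeline failed at stage 'write_outputs': %s",
           conditionMessage(e))
    })
  }
  invisible(result)
}

# Per-quantity truth recovery: true value, per-survey estimates and whether
# each CI covers truth, and whether the corrected difference CI covers the
# true difference (zero: both surveys draw from one population).
recovery_table <- function(estimates, differences, realized_prevalence) {
  rp <- realized_prevalence
  rows <- lapply(seq_len(nrow(differences)), function(i) {
    qn <- differences$quantity[i]
    parts <- strsplit(qn, ".", fixed = TRUE)[[1]]
    oc <- parts[1]; rc <- if (length(parts) > 1) parts[2] else NA
    hit <- rp$outcome == oc & rp$recency == rc
    if (!any(hit, na.rm = TRUE)) return(NULL)  # quantity outside the truth grid
    truth_pct <- 100 * rp$prevalence[which(hit)]
    ea <- estimates[estimates$outcome == oc & estimates$recency == rc &
                      estimates$survey == "A", ]
    eb <- estimates[estimates$outcome == oc & estimates$recency == rc &
                      estimates$survey == "B", ]
    data.frame(
      quantity = qn, truth_pct = truth_pct,
      est_a = 100 * ea$p_hat,
      covered_a = 100 * ea$ci_low <= truth_pct & truth_pct <= 100 * ea$ci_high,
      est_b = 100 * eb$p_hat,
      covered_b = 100 * eb$ci_low <= truth_pct & truth_pct <= 100 * eb$ci_high,
      true_diff = 0,
      diff_point = differences$diff_point[i],
      cci_covers_true_diff = differences$cci_low[i] <= 0 &
        0 <= differences$cci_high[i],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Truth-recovery report for a written pipeline run
#'
#' Reads the result tables of a [run_pipeline()] output directory and scores
#' every comparison quantity against the recorded population truth.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return data.frame, one row per comparison quantity: truth, per-survey
#'   estimates with coverage flags, and corrected-interval coverage of the
#'   true (zero) difference.
#' @export
recovery_report <- function(run_dir) {
  need <- file.path(run_dir, c("estimates.csv", "differences.csv",
                               "truth_realized.csv"))
  if (!all(file.exists(need))) {
    fail("run directory lacks required tables (population truth missing?)")
  }
  recovery_table(utils::read.csv(need[1]), utils::read.csv(need[2]),
                 utils::read.csv(need[3]))
}
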