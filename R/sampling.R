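# Survey draws from the synthetic population: a stratified two-stage
# probability sample with logistic nonresponse and class-based weight
# adjustment, and an opt-in panel with covariate-dependent self-selection
# and raking-calibrated weights.

#' Specify a survey design
#'
#' @param kind `"probability_clustered"` or `"optin_panel"`.
#' @param n_strata,psus_per_stratum population clustering (probability kind):
#'   persons are partitioned at random into balanced strata and PSUs.
#' @param sample_psus_per_stratum PSUs drawn without replacement per stratum;
#'   at least 2 so design variances exist.
#' @param respondents_per_psu persons drawn without replacement within each
#'   sampled PSU (capped at PSU size).
#' @param nonresponse_model named log-odds vector (same naming scheme as the
#'   outcome models, `(Intercept)` required) giving each sampled person's
#'   response propensity; NULL means full response.
#' @param selection_model (opt-in kind) named log-odds vector giving each
#'   person's probability of joining the panel.
#' @param raking_margins (opt-in kind) character vector of covariates whose
#'   weighted distribution is calibrated to the population margins.
#' @param seed default seed recorded with the design (draw functions take an
#'   explicit seed that overrides it).
#' @return object of class `survey_design_spec`.
#' @export
survey_design_spec <- function(kind,
                               n_strata = NULL, psus_per_stratum = NULL,
                               sample_psus_per_stratum = NULL,
                               respondents_per_psu = NULL,
                               nonresponse_model = NULL,
                               selection_model = NULL,
                               raking_margins = NULL,
                               seed = NULL) {
  kind <- match.arg(kind, c("probability_clustered", "optin_panel"))
  if (kind == "probability_clustered") {
    stopifnot(n_strata >= 1, psus_per_stratum >= 2,
              respondents_per_psu >= 1)
    if (sample_psus_per_stratum < 2) {
      fail("at least 2 sampled PSUs per stratum are required for variance estimation")
    }
    if (sample_psus_per_stratum > psus_per_stratum) {
      fail("cannot sample %d PSUs from strata holding %d",
           sample_psus_per_stratum, psus_per_stratum)
    }
  } else {
    if (!is.null(n_strata) || !is.null(psus_per_stratum)) {
      fail("optin_panel has no strata/PSU structure")
    }
    if (is.null(selection_model)) fail("optin_panel requires a selection_model")
  }
  structure(list(kind = kind, n_strata = n_strata,
                 psus_per_stratum = psus_per_stratum,
                 sample_psus_per_stratum = sample_psus_per_stratum,
                 respondents_per_psu = respondents_per_psu,
                 nonresponse_model = nonresponse_model,
                 selection_model = selection_model,
                 raking_margins = raking_margins,
                 seed = seed),
            class = "survey_design_spec")
}

# Columns the survey instruments emit (truth-only fields like the
# heavy-alcohol flag stay in the population; harmonization re-derives them).
instrument_columns <- function(pop) {
  keep <- c("person_id", "age_group", "sex", "race", "income", "education",
            "marital", "employment", "insurance", "cigarette", "cannabis",
            "stimulant", "benzodiazepine", "moud", "hospitalization",
            "health", "drinks_per_week",
            "heroin_past_year", "heroin_past_month",
            "imf_past_year", "imf_past_month")
  intersect(keep, names(pop))
}

# Emit the instrument view of sampled rows: blank the cigarette item where
# the population carries a blank flag.
as_instrument <- function(pop, rows) {
  samp <- pop[rows, instrument_columns(pop), drop = FALSE]
  if ("cigarette_blank" %in% names(pop)) {
    samp$cigarette[pop$cigarette_blank[rows]] <- NA_character_
  }
  samp
}

# Balanced random partition of n units into k groups, seeded by caller.
balanced_groups <- function(n, k) sample(rep_len(seq_len(k), n))

#' Draw a stratified two-stage probability sample
#'
#' Persons are partitioned at random into balanced strata and PSUs; PSUs are
#' drawn without replacement within each stratum, persons without replacement
#' within each sampled PSU. Base weights are inverse inclusion probabilities.
#' If a nonresponse model is given, sampled persons respond with logistic
#' propensity and weights are adjusted by the inverse weighted response rate
#' within cells of the model's covariates, so the weight mass of
#' nonrespondents is redistributed to responding members of the same class.
#'
#' @param population population table from [generate_population()].
#' @param design a probability-kind [survey_design_spec()].
#' @param seed integer seed for this draw.
#' @return a [survey_dataset()] of kind `probability_clustered`.
#' @export
draw_probability_sample <- function(population, design, seed = design$seed) {
  stopifnot(inherits(design, "survey_design_spec"))
  if (design$kind != "probability_clustered") {
    fail("design kind must be probability_clustered")
  }
  if (is.null(seed)) fail("a seed is required")
  set.seed(child_seed(seed, "probability_sample"))
  n <- nrow(population)
  stratum <- balanced_groups(n, design$n_strata)
  psu <- integer(n)
  for (h in seq_len(design$n_strata)) {
    idx <- which(stratum == h)
    if (length(idx) < design$psus_per_stratum) {
      fail("stratum %d holds %d persons, fewer than its %d PSUs",
           h, length(idx), design$psus_per_stratum)
    }
    psu[idx] <- balanced_groups(length(idx), design$psus_per_stratum)
  }
  rows <- integer(0); w <- numeric(0)
  m <- design$sample_psus_per_stratum
  for (h in seq_len(design$n_strata)) {
    in_h <- which(stratum == h)
    psus_h <- sort(unique(psu[in_h]))
    if (length(psus_h) < m) {
      fail("stratum %d has %d PSUs, fewer than the %d to sample",
           h, length(psus_h), m)
    }
    take_psus <- sample(psus_h, m)
    for (j in take_psus) {
      members <- in_h[psu[in_h] == j]
      k <- min(design$respondents_per_psu, length(members))
      take <- if (length(members) == 1) members else sample(members, k)
      rows <- c(rows, take)
      w <- c(w, rep((length(psus_h) / m) * (length(members) / k), k))
    }
  }
  samp <- as_instrument(population, rows)
  samp$stratum <- stratum[rows]
  samp$psu <- psu[rows]
  samp$weight <- w
  dropped_psus <- character(0)
  if (!is.null(design$nonresponse_model)) {
    pr <- inv_logit(linear_predictor(samp, design$nonresponse_model))
    respond <- stats::runif(nrow(samp)) < pr
    cls <- nonresponse_classes(samp, design$nonresponse_model)
    tot_s <- tapply(samp$weight, cls, sum)
    tot_r <- tapply(samp$weight * respond, cls, sum)
    empty <- names(tot_r)[is.na(tot_r) | tot_r == 0]
    if (length(empty) > 0) {
      fail("nonresponse left adjustment class(es) empty: %s",
           paste(empty, collapse = ", "))
    }
    adj <- tot_s / tot_r
    before <- unique(samp[c("stratum", "psu")])
    samp$weight <- as.numeric(samp$weight * adj[cls])
    samp <- samp[respond, , drop = FALSE]
    after <- unique(samp[c("stratum", "psu")])
    lost <- !paste(before$stratum, before$psu) %in% paste(after$stratum, after$psu)
    if (any(lost)) {
      dropped_psus <- paste(before$stratum[lost], before$psu[lost], sep = "/")
    }
  }
  names(samp)[names(samp) == "person_id"] <- "respondent_id"
  rownames(samp) <- NULL
  survey_dataset(samp, kind = "probability_clustered",
                 stratum_col = "stratum", psu_col = "psu", seed = seed,
                 meta = list(design = "stratified two-stage, SRSWOR at both stages",
                             n_strata = design$n_strata,
                             sample_psus_per_stratum = m,
                             dropped_psus = dropped_psus))
}

nonresponse_classes <- function(tab, model) {
  covs <- unique(vapply(setdiff(names(model), "(Intercept)"),
                        function(x) strsplit(x, "=", fixed = TRUE)[[1]][1],
                        character(1)))
  if (length(covs) == 0) return(rep("all", nrow(tab)))
  interaction(tab[covs], drop = TRUE, sep = ":")
}

#' Draw an opt-in panel sample
#'
#' Each person joins the panel independently with logistic self-selection
#' probability; initial weights are uniform (population size over realized
#' sample size), then raked to the population margins of the design's
#' `raking_margins` covariates. Respondents are split across two pooled waves
#' and carry no strata/PSU labels: each respondent is its own sampling unit.
#'
#' @inheritParams draw_probability_sample
#' @param design an optin-kind [survey_design_spec()].
#' @param rake_tol,rake_max_iter convergence control passed to [rake_weights()].
#' @return a [survey_dataset()] of kind `optin_panel`.
#' @export
draw_optin_sample <- function(population, design, seed = design$seed,
                              rake_tol = 1e-8, rake_max_iter = 100) {
  stopifnot(inherits(design, "survey_design_spec"))
  if (design$kind != "optin_panel") fail("design kind must be optin_panel")
  if (is.null(seed)) fail("a seed is required")
  set.seed(child_seed(seed, "optin_sample"))
  n <- nrow(population)
  pr <- inv_logit(linear_predictor(population, design$selection_model))
  join <- stats::runif(n) < pr
  if (!any(join)) fail("no person joined the panel; selection model too restrictive")
  samp <- as_instrument(population, which(join))
  samp$wave <- sample(c("wave1", "wave2"), nrow(samp), replace = TRUE)
  samp$weight <- n / nrow(samp)
  names(samp)[names(samp) == "person_id"] <- "respondent_id"
  rownames(samp) <- NULL
  ds <- survey_dataset(samp, kind = "optin_panel", seed = seed,
                       meta = list(design = "opt-in panel, two pooled waves",
                                   selection_rate = mean(join)))
  if (!is.null(design$raking_margins)) {
    margins <- population_margins(population, design$raking_margins)
    ds <- rake_weights(ds, margins, total = n,
                       tol = rake_tol, max_iter = rake_max_iter)
  }
  ds
}

#' Population margins for calibration
#'
#' @param population population table.
#' @param covariates character vector of covariate columns.
#' @return named list of named share vectors (each sums to 1).
#' @export
population_margins <- function(population, covariates) {
  out <- lapply(covariates, function(cv) {
    if (!cv %in% names(population)) fail("margin covariate '%s' not found", cv)
    tab <- table(population[[cv]], useNA = "no")
    prop <- as.numeric(tab) / sum(tab)
    names(prop) <- names(tab)
    prop
  })
  names(out) <- covariates
  out
}
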