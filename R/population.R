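# Synthetic latent population with known truth. Covariates are categorical
# with configurable margins (independent by default, with an optional
# pairwise log-odds association knob); past-year heroin and IMF use are
# Bernoulli draws from per-outcome logistic models on the covariates;
# recency among past-year users is a two-level split (past month vs.
# 2-12 months). The realized prevalences are recomputed by exhaustive count
# over the table, so downstream recovery is tested against exact truth.

#' Default covariate margins for the synthetic population
#'
#' Margins are illustrative, chosen to resemble the US adult population the
#' two emulated surveys weight to. Multi-level covariates carry named
#' probability vectors; binary flags use `c(no =, yes =)`.
#' @return named list of named probability vectors, each summing to 1.
#' @export
default_covariate_spec <- function() {
  list(
    age_group = c("18-25" = 0.13, "26-34" = 0.16, "35-49" = 0.24,
                  "50-64" = 0.25, "65+" = 0.22),
    sex = c(male = 0.48, female = 0.52),
    race = c("non-Hispanic White" = 0.600, "non-Hispanic Black" = 0.120,
             "Hispanic" = 0.170, "Asian" = 0.060, "Native American" = 0.010,
             "Native Hawaiian" = 0.005, "Multiple races" = 0.025,
             "Other" = 0.010),
    income = c("<$50,000" = 0.38, "$50,000-$74,999" = 0.17,
               ">=$75,000" = 0.45),
    education = c("less than high school" = 0.10, "high school" = 0.28,
                  "some college" = 0.30, "college graduate" = 0.32),
    marital = c(married = 0.50, never_married = 0.30,
                previously_married = 0.20),
    employment = c(none = 0.40, past_week = 0.60),
    insurance = c(private = 0.55, public = 0.35, none = 0.10),
    cigarette = c("every day" = 0.11, "some days" = 0.04,
                  "not at all" = 0.85),
    cannabis = c(no = 0.82, yes = 0.18),
    stimulant = c(no = 0.97, yes = 0.03),
    benzodiazepine = c(no = 0.98, yes = 0.02),
    heavy_alcohol = c(no = 0.94, yes = 0.06),
    moud = c(no = 0.99, yes = 0.01),
    hospitalization = c(no = 0.92, yes = 0.08),
    health = c("fair/poor" = 0.17, "good" = 0.30, "very good" = 0.33,
               "excellent" = 0.20)
  )
}

#' Default outcome-model coefficients (log-odds)
#'
#' Illustrative coefficient vectors for the past-year heroin and IMF latent
#' outcomes. Names are either a bare binary covariate (effect of its "yes"
#' level) or `"covariate=level"` for a specific level of a multi-level
#' covariate; `(Intercept)` is required. Defaults put either-use prevalence
#' near the half-percent scale typical of national opioid surveillance.
#' @return list with elements `heroin` and `imf`, each a named numeric vector.
#' @export
default_outcome_coefficients <- function() {
  shared <- c(
    "stimulant" = 2.40, "benzodiazepine" = 1.60, "moud" = 2.50,
    "cigarette=not at all" = -1.40, "cigarette=some days" = -0.20,
    "employment=past_week" = -0.45, "insurance=public" = 0.60,
    "insurance=none" = 0.90, "age_group=35-49" = 0.40,
    "age_group=50-64" = 0.10, "age_group=65+" = -1.20,
    "sex=female" = -0.55, "hospitalization" = 0.50
  )
  list(heroin = c("(Intercept)" = -5.42, shared),
       imf = c("(Intercept)" = -5.27, shared))
}

#' Define a synthetic population truth
#'
#' @param pop_size number of persons.
#' @param covariate_spec margins per covariate; see
#'   [default_covariate_spec()].
#' @param outcome_coefficients per-outcome logistic coefficients; see
#'   [default_outcome_coefficients()].
#' @param recency_split named list/vector: probability that a past-year user
#'   is a past-month user, per outcome (`heroin`, `imf`).
#' @param associations optional list of pairwise log-odds tilts, each
#'   `list(a = <binary covariate>, b = <binary covariate>, log_or = <real>)`;
#'   the pair's joint is tilted to the stated odds ratio while both margins
#'   are preserved.
#' @param cigarette_blank_rate share of true "not at all" cigarette responses
#'   left blank on the instrument (recovered by the blank->"not at all" rule).
#' @return object of class `population_truth`.
#' @export
population_truth <- function(pop_size = 200000,
                             covariate_spec = default_covariate_spec(),
                             outcome_coefficients = default_outcome_coefficients(),
                             recency_split = c(heroin = 0.65, imf = 0.45),
                             associations = list(
                               list(a = "stimulant", b = "benzodiazepine",
                                    log_or = 1.5)),
                             cigarette_blank_rate = 0.05) {
  stopifnot(pop_size >= 1)
  for (nm in names(covariate_spec)) {
    p <- covariate_spec[[nm]]
    if (is.null(names(p)) || any(p < 0)) {
      fail("covariate '%s': margins must be named and nonnegative", nm)
    }
    if (abs(sum(p) - 1) > 1e-12) {
      fail("covariate '%s': margins sum to %.15f, not 1", nm, sum(p))
    }
  }
  for (oc in names(outcome_coefficients)) {
    b <- outcome_coefficients[[oc]]
    if (any(!is.finite(b))) fail("non-finite coefficient in outcome '%s'", oc)
    if (!"(Intercept)" %in% names(b)) {
      fail("outcome '%s' lacks an (Intercept)", oc)
    }
  }
  rs <- unlist(recency_split)
  if (any(rs < 0 | rs > 1)) fail("recency_split must lie in [0,1]")
  if (cigarette_blank_rate < 0 || cigarette_blank_rate > 1) {
    fail("cigarette_blank_rate must lie in [0,1]")
  }
  for (a in associations) {
    for (cv in c(a$a, a$b)) {
      p <- covariate_spec[[cv]]
      if (is.null(p) || !setequal(names(p), c("no", "yes"))) {
        fail("association covariate '%s' must be binary (no/yes)", cv)
      }
    }
  }
  structure(list(pop_size = as.integer(pop_size),
                 covariate_spec = covariate_spec,
                 outcome_coefficients = outcome_coefficients,
                 recency_split = rs,
                 associations = associations,
                 cigarette_blank_rate = cigarette_blank_rate),
            class = "population_truth")
}

# Joint cell probabilities of two binary covariates with fixed margins and a
# log-odds-ratio tilt. Returns c(p00, p01, p10, p11) for (a,b) in {no,yes}^2.
joint_from_margins_or <- function(pa, pb, log_or) {
  or <- exp(log_or)
  if (abs(or - 1) < 1e-12) {
    p11 <- pa * pb
  } else {
    # p11 solves or = p11 (1 - pa - pb + p11) / ((pa - p11)(pb - p11))
    A <- or - 1
    B <- -(1 + (pa + pb) * (or - 1))
    C <- or * pa * pb
    disc <- B^2 - 4 * A * C
    p11 <- (-B - sqrt(disc)) / (2 * A)
  }
  p11 <- min(max(p11, 0), min(pa, pb))
  c(p00 = 1 - pa - pb + p11, p01 = pb - p11, p10 = pa - p11, p11 = p11)
}

# Linear predictor for one outcome over a covariate table.
linear_predictor <- function(tab, beta) {
  eta <- rep(unname(beta["(Intercept)"]), nrow(tab))
  for (nm in setdiff(names(beta), "(Intercept)")) {
    if (grepl("=", nm, fixed = TRUE)) {
      parts <- strsplit(nm, "=", fixed = TRUE)[[1]]
      cov <- parts[1]; lev <- paste(parts[-1], collapse = "=")
    } else {
      cov <- nm; lev <- "yes"
    }
    if (!cov %in% names(tab)) fail("coefficient '%s': covariate not present", nm)
    eta <- eta + beta[[nm]] * (as.character(tab[[cov]]) == lev)
  }
  eta
}

#' Generate the synthetic population
#'
#' Draws covariates from the stated margins (with any pairwise association
#' tilts), realizes past-year heroin and IMF use by Bernoulli draws from the
#' per-outcome logistic models, splits past-year users into past-month vs.
#' 2-12-months by the recency split, and emits the raw instrument fields
#' (weekly drinks consistent with the heavy-alcohol flag and sex; cigarette
#' blanks among true "not at all" responses). Identical `(truth, seed)` give
#' a byte-identical table.
#'
#' @param truth a [population_truth()].
#' @param seed integer master seed for the population stream.
#' @return list with `population` (data.frame, one row per person) and
#'   `realized_prevalence` (exhaustive-count prevalences, see
#'   [realized_prevalence()]).
#' @export
generate_population <- function(truth, seed) {
  stopifnot(inherits(truth, "population_truth"))
  set.seed(child_seed(seed, "population"))
  n <- truth$pop_size
  spec <- truth$covariate_spec
  pop <- data.frame(person_id = seq_len(n))
  assoc_b <- vapply(truth$associations, function(a) a$b, character(1))
  for (nm in names(spec)) {
    if (nm %in% assoc_b) next  # drawn jointly with its partner below
    p <- spec[[nm]]
    pop[[nm]] <- sample(names(p), n, replace = TRUE, prob = p)
  }
  for (a in truth$associations) {
    pa <- spec[[a$a]][["yes"]]; pb <- spec[[a$b]][["yes"]]
    j <- joint_from_margins_or(pa, pb, a$log_or)
    is_a <- pop[[a$a]] == "yes"
    p_b_given_a <- j[["p11"]] / pa
    p_b_given_nota <- j[["p01"]] / (1 - pa)
    pr <- ifelse(is_a, p_b_given_a, p_b_given_nota)
    pop[[a$b]] <- ifelse(stats::runif(n) < pr, "yes", "no")
  }
  # outcome draws on the true covariates (before instrument blanking)
  for (oc in c("heroin", "imf")) {
    eta <- linear_predictor(pop, truth$outcome_coefficients[[oc]])
    p <- inv_logit(eta)
    if (any(p < 0 | p > 1)) fail("outcome probability outside [0,1]")
    py <- stats::runif(n) < p
    pm <- py & (stats::runif(n) < truth$recency_split[[oc]])
    pop[[paste0(oc, "_past_year")]] <- py
    pop[[paste0(oc, "_past_month")]] <- pm
  }
  # weekly drinks consistent with the heavy-alcohol flag and NIAAA thresholds
  if (all(c("sex", "heavy_alcohol") %in% names(pop))) {
    thr <- ifelse(pop$sex == "male", 15, 8)
    heavy <- pop$heavy_alcohol == "yes"
    pop$drinks_per_week <- ifelse(heavy, thr + stats::rexp(n, rate = 1 / 6),
                                  stats::runif(n, 0, thr * 0.9))
  }
  # instrument blanks among true "not at all" cigarette responses; the blank
  # is an instrument artifact, so the population keeps the true value and a
  # flag the survey draws apply when emitting instrument columns
  if ("cigarette" %in% names(pop)) {
    pop$cigarette_blank <- pop$cigarette == "not at all" &
      stats::runif(n) < truth$cigarette_blank_rate
  }
  list(population = pop, realized_prevalence = realized_prevalence(pop))
}

#' Exhaustive-count prevalences of a realized population
#'
#' @param pop population table from [generate_population()].
#' @return data.frame with one row per outcome (heroin, imf, either) and
#'   recency window (past_year, past_month, months_2_12), column `prevalence`.
#' @export
realized_prevalence <- function(pop) {
  h_py <- pop$heroin_past_year; h_pm <- pop$heroin_past_month
  i_py <- pop$imf_past_year; i_pm <- pop$imf_past_month
  ind <- list(
    heroin = list(past_year = h_py, past_month = h_pm,
                  months_2_12 = h_py & !h_pm),
    imf = list(past_year = i_py, past_month = i_pm,
               months_2_12 = i_py & !i_pm),
    either = list(past_year = h_py | i_py, past_month = h_pm | i_pm,
                  months_2_12 = (h_py | i_py) & !(h_pm | i_pm))
  )
  out <- do.call(rbind, lapply(names(ind), function(oc) {
    do.call(rbind, lapply(names(ind[[oc]]), function(rc) {
      data.frame(outcome = oc, recency = rc,
                 prevalence = mean(ind[[oc]][[rc]]))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Model-implied marginal prevalence by exhaustive enumeration
#'
#' Computes the expected past-year prevalence of an outcome under the truth's
#' logistic model by enumerating the joint distribution of the covariates the
#' model actually uses (other covariates integrate out). Association pairs are
#' supported when both members are enumerated or both unused. Cost is
#' exponential in the number of used covariates; intended as an exact oracle
#' at model sizes where enumeration is feasible.
#'
#' @param truth a [population_truth()].
#' @param outcome `"heroin"`, `"imf"` or `"either"` (either assumes the two
#'   outcomes are conditionally independent given covariates, as generated).
#' @return expected past-year prevalence (a probability).
#' @export
model_implied_prevalence <- function(truth, outcome = "either") {
  outcome <- match.arg(outcome, c("heroin", "imf", "either"))
  betas <- truth$outcome_coefficients
  used <- unique(unlist(lapply(betas, function(b) {
    nm <- setdiff(names(b), "(Intercept)")
    vapply(nm, function(x) strsplit(x, "=", fixed = TRUE)[[1]][1], character(1))
  })))
  for (a in truth$associations) {
    both <- c(a$a, a$b) %in% used
    if (any(both) && !all(both)) {
      fail("association (%s, %s) straddles the used covariate set; cannot enumerate",
           a$a, a$b)
    }
  }
  spec <- truth$covariate_spec[used]
  cells <- expand.grid(lapply(spec, names), stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  # cell probability: product of margins, corrected for association pairs
  pr <- rep(1, nrow(cells))
  assoc_covs <- unlist(lapply(truth$associations, function(a) c(a$a, a$b)))
  for (nm in used) {
    if (nm %in% assoc_covs) next
    pr <- pr * spec[[nm]][cells[[nm]]]
  }
  for (a in truth$associations) {
    if (!all(c(a$a, a$b) %in% used)) next
    j <- joint_from_margins_or(spec[[a$a]][["yes"]], spec[[a$b]][["yes"]],
                               a$log_or)
    key <- paste0("p", as.integer(cells[[a$a]] == "yes"),
                  as.integer(cells[[a$b]] == "yes"))
    pr <- pr * j[key]
  }
  p_out <- function(oc) inv_logit(linear_predictor(cells, betas[[oc]]))
  p <- switch(outcome,
              heroin = p_out("heroin"),
              imf = p_out("imf"),
              either = 1 - (1 - p_out("heroin")) * (1 - p_out("imf")))
  sum(pr * p)
}
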