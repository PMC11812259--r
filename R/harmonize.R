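# Variable-construction rules shared by both surveys: recency classification,
# the combined heroin-or-IMF outcome, heavy-alcohol thresholds, race collapse,
# and the cigarette-blank rule. These mirror the harmonized analytic dictionary
# used for cross-survey comparison; they never drop records or touch weights.

#' Ordered recency levels
#'
#' Recency of use is a three-level ordered factor:
#' `none < months_2_12 < past_month`.
#' @export
recency_levels <- function() c("none", "months_2_12", "past_month")

#' Classify recency of use from past-year and past-month indicators
#'
#' Both surveys ask categorical recency; the analysis uses a two-level split
#' within past-year users (past month vs. 2-12 months ago). Vectorized.
#'
#' @param past_year_use logical; any use in the past 12 months.
#' @param past_month_use logical; any use in the past month. Must imply
#'   `past_year_use`; a past-month report without past-year use is a data
#'   consistency error.
#' @param id optional respondent identifiers used in error messages.
#' @return factor with levels [recency_levels()], ordered.
#' @export
#' @examples
#' classify_recency(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
classify_recency <- function(past_year_use, past_month_use, id = NULL) {
  stopifnot(is.logical(past_year_use), is.logical(past_month_use),
            length(past_year_use) == length(past_month_use))
  bad <- which(past_month_use & !past_year_use)
  if (length(bad) > 0) {
    who <- if (!is.null(id)) paste(id[bad], collapse = ", ") else
      paste(bad, collapse = ", ")
    fail("past-month use without past-year use for respondent(s): %s", who)
  }
  out <- ifelse(past_month_use, "past_month",
                ifelse(past_year_use, "months_2_12", "none"))
  factor(out, levels = recency_levels(), ordered = TRUE)
}

#' Most recent use of either of two substances
#'
#' The combined "either heroin or IMF" outcome takes the more recent of the
#' two recencies, i.e. the maximum under `none < months_2_12 < past_month`.
#'
#' @param heroin_recency,imf_recency factors (or strings) on
#'   [recency_levels()].
#' @return ordered factor, elementwise maximum.
#' @export
derive_either <- function(heroin_recency, imf_recency) {
  lv <- recency_levels()
  a <- as.integer(factor(as.character(heroin_recency), levels = lv))
  b <- as.integer(factor(as.character(imf_recency), levels = lv))
  if (any(is.na(a)) || any(is.na(b))) fail("invalid recency value")
  factor(lv[pmax(a, b)], levels = lv, ordered = TRUE)
}

#' Heavy alcohol use classification
#'
#' NIAAA weekly thresholds: at least 15 drinks per week for men, at least 8
#' for women.
#'
#' @param drinks_per_week nonnegative numeric.
#' @param sex "male" or "female" (recycled if scalar).
#' @return logical vector.
#' @export
classify_heavy_alcohol <- function(drinks_per_week, sex) {
  stopifnot(is.numeric(drinks_per_week), all(is.finite(drinks_per_week)))
  if (any(drinks_per_week < 0)) fail("negative drinks_per_week")
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female"))) fail("sex must be 'male' or 'female'")
  if (length(sex) == 1) sex <- rep(sex, length(drinks_per_week))
  thr <- ifelse(sex == "male", 15, 8)
  drinks_per_week >= thr
}

race_input_vocabulary <- function() {
  c("non-Hispanic White", "non-Hispanic Black", "Hispanic",
    "Native American", "Native Hawaiian", "Asian", "Multiple races", "Other")
}

race_output_vocabulary <- function() {
  c("non-Hispanic White", "non-Hispanic Black", "Hispanic",
    "another non-Hispanic race")
}

#' Collapse detailed race/ethnicity to the 4-level modeling vocabulary
#'
#' Sparse categories (Native American, Native Hawaiian, Asian, Multiple races,
#' Other) are combined into a single "another non-Hispanic race" group;
#' non-Hispanic White, non-Hispanic Black and Hispanic pass through.
#'
#' @param category character vector in the documented input vocabulary.
#' @return factor on the 4-level output vocabulary.
#' @export
collapse_race <- function(category) {
  category <- as.character(category)
  vocab <- race_input_vocabulary()
  unknown <- setdiff(unique(category), vocab)
  if (length(unknown) > 0) {
    fail("unknown race category '%s'; expected one of: %s",
         unknown[1], paste(vocab, collapse = ", "))
  }
  keep <- c("non-Hispanic White", "non-Hispanic Black", "Hispanic")
  out <- ifelse(category %in% keep, category, "another non-Hispanic race")
  factor(out, levels = race_output_vocabulary())
}

cigarette_levels <- function() c("every day", "some days", "not at all")

#' Resolve blank cigarette-use responses
#'
#' Respondents who left the cigarette item blank are included in the
#' "not at all" group for modeling. Idempotent.
#'
#' @param value character vector on `{every day, some days, not at all}` or NA.
#' @return factor on [cigarette_levels()].
#' @export
resolve_cigarette_blank <- function(value) {
  value <- as.character(value)
  ok <- is.na(value) | value %in% cigarette_levels()
  if (!all(ok)) fail("invalid cigarette value '%s'", value[!ok][1])
  value[is.na(value)] <- "not at all"
  factor(value, levels = cigarette_levels())
}

#' Harmonize a raw survey dataset to the analytic dictionary
#'
#' Applies the shared variable-construction rules to the raw instrument
#' columns of a [survey_dataset()]: recency classification for heroin and IMF
#' and the derived either-use outcome, heavy-alcohol flag from weekly drinks
#' and sex, race collapse, and the cigarette-blank rule. Record count and
#' weights are unchanged.
#'
#' @param ds a [survey_dataset()] whose data carry the raw columns
#'   `heroin_past_year`, `heroin_past_month`, `imf_past_year`,
#'   `imf_past_month`, `drinks_per_week`, `sex`, `race`, `cigarette`.
#' @return the same survey_dataset with analytic columns `heroin_recency`,
#'   `imf_recency`, `either_recency`, `heavy_alcohol`, `race4`,
#'   `cigarette3` added.
#' @export
harmonize_survey <- function(ds) {
  stopifnot(inherits(ds, "survey_dataset"))
  d <- ds$data
  need <- c("heroin_past_year", "heroin_past_month", "imf_past_year",
            "imf_past_month", "drinks_per_week", "sex", "race", "cigarette")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0) {
    fail("raw columns missing for harmonization: %s",
         paste(missing_cols, collapse = ", "))
  }
  id <- if ("respondent_id" %in% names(d)) d$respondent_id else seq_len(nrow(d))
  d$heroin_recency <- classify_recency(d$heroin_past_year, d$heroin_past_month, id)
  d$imf_recency <- classify_recency(d$imf_past_year, d$imf_past_month, id)
  d$either_recency <- derive_either(d$heroin_recency, d$imf_recency)
  d$heavy_alcohol <- factor(
    ifelse(classify_heavy_alcohol(d$drinks_per_week, as.character(d$sex)),
           "yes", "no"), levels = c("no", "yes"))
  d$race4 <- collapse_race(d$race)
  d$cigarette3 <- resolve_cigarette_blank(d$cigarette)
  ds$data <- d
  ds$harmonized <- TRUE
  ds
}
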