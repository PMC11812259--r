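# SurveyDataset: a respondent-level table plus the design metadata every
# estimator needs (kind, stratum/PSU columns, weight column, seed).

#' Construct a survey dataset
#'
#' Bundles respondent records with design metadata. Two kinds are supported:
#' `probability_clustered` (stratified two-stage sample; records carry stratum
#' and PSU labels, and every represented stratum must hold at least two
#' sampled PSUs so design-based variances exist) and `optin_panel`
#' (self-selected panel; each respondent is its own sampling unit and the
#' stratum/PSU columns are absent).
#'
#' @param data data.frame of respondent records, one row per respondent.
#' @param kind `"probability_clustered"` or `"optin_panel"`.
#' @param weight_col name of the positive analytic-weight column.
#' @param stratum_col,psu_col design columns (required for
#'   `probability_clustered`, must be NULL for `optin_panel`).
#' @param seed integer seed recorded for provenance (optional).
#' @param meta free-form named list of provenance metadata.
#' @return an object of class `survey_dataset`.
#' @export
survey_dataset <- function(data, kind, weight_col = "weight",
                           stratum_col = NULL, psu_col = NULL,
                           seed = NULL, meta = list()) {
  kind <- match.arg(kind, c("probability_clustered", "optin_panel"))
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0) fail("survey dataset has no records")
  if (!weight_col %in% names(data)) fail("weight column '%s' not found", weight_col)
  w <- data[[weight_col]]
  if (!is.numeric(w) || any(!is.finite(w)) || any(w <= 0)) {
    fail("weights must be finite and strictly positive")
  }
  if (kind == "probability_clustered") {
    if (is.null(stratum_col) || is.null(psu_col)) {
      fail("probability_clustered requires stratum_col and psu_col")
    }
    if (!all(c(stratum_col, psu_col) %in% names(data))) {
      fail("stratum/PSU columns not found in data")
    }
    npsu <- tapply(data[[psu_col]], data[[stratum_col]],
                   function(x) length(unique(x)))
    if (any(npsu < 2)) {
      fail("stratum %s has a single sampled PSU; >= 2 required for variance estimation",
           paste(names(npsu)[npsu < 2], collapse = ", "))
    }
  } else {
    if (!is.null(stratum_col) || !is.null(psu_col)) {
      fail("optin_panel has no strata/PSU structure")
    }
  }
  structure(list(data = data, kind = kind, weight_col = weight_col,
                 stratum_col = stratum_col, psu_col = psu_col,
                 seed = seed, meta = meta, harmonized = FALSE),
            class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(sprintf("<survey_dataset: %s>\n", x$kind))
  cat(sprintf("  respondents: %d, weighted total: %.1f\n",
              nrow(x$data), sum(x$data[[x$weight_col]])))
  if (x$kind == "probability_clustered") {
    cat(sprintf("  strata: %d, sampled PSUs: %d\n",
                length(unique(x$data[[x$stratum_col]])),
                nrow(unique(x$data[c(x$stratum_col, x$psu_col)]))))
  }
  if (isTRUE(x$harmonized)) cat("  harmonized: yes\n")
  invisible(x)
}

ds_weights <- function(ds) ds$data[[ds$weight_col]]

#' Write a survey dataset as CSV plus a JSON design sidecar
#'
#' The records go to `<path>.csv`; the design metadata (kind, design column
#' names, weight column, seed, extra metadata) to `<path>.json`, so a dataset
#' round-trips through plain text.
#'
#' @param ds a [survey_dataset()].
#' @param path file stem (without extension).
#' @return invisibly, the two file paths.
#' @export
write_survey_dataset <- function(ds, path) {
  csv <- paste0(path, ".csv")
  side <- paste0(path, ".json")
  utils::write.csv(ds$data, csv, row.names = FALSE)
  meta <- list(kind = ds$kind, weight_col = ds$weight_col,
               stratum_col = ds$stratum_col, psu_col = ds$psu_col,
               seed = ds$seed, harmonized = isTRUE(ds$harmonized),
               meta = ds$meta)
  jsonlite::write_json(meta, side, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(c(csv = csv, sidecar = side))
}

#' Read a survey dataset written by [write_survey_dataset()]
#' @param path file stem (without extension).
#' @return a [survey_dataset()].
#' @export
read_survey_dataset <- function(path) {
  d <- utils::read.csv(paste0(path, ".csv"), stringsAsFactors = FALSE)
  m <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ds <- survey_dataset(d, kind = m$kind, weight_col = m$weight_col,
                       stratum_col = m$stratum_col, psu_col = m$psu_col,
                       seed = m$seed,
                       meta = if (is.null(m$meta)) list() else as.list(m$meta))
  ds$harmonized <- isTRUE(m$harmonized)
  ds
}
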