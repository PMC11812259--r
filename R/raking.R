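# Raking (iterative proportional fitting) of analytic weights to known
# population margins -- the calibration step that makes an opt-in panel
# represent the target population on the raked covariates.

#' Rake survey weights to population margins
#'
#' Iterative proportional fitting: cycles over the margin list, multiplying
#' each category's weights by the ratio of its target weighted total to its
#' current weighted total, until every weighted category share is within
#' `tol` of its target (and the grand total is within `tol` relative of
#' `total`), or `max_iter` passes are exhausted. Weights stay strictly
#' positive. If the margins are already satisfied the weights are returned
#' unchanged.
#'
#' @param ds a [survey_dataset()].
#' @param margins named list: for each covariate column, a named vector of
#'   target population shares (summing to 1). Every category with positive
#'   target share must be present in the sample.
#' @param total target population total for the weights (defaults to the
#'   current weight sum).
#' @param tol maximum absolute deviation of any weighted share from target.
#' @param max_iter maximum IPF passes over the margin list.
#' @return the dataset with calibrated weights; raking diagnostics
#'   (iterations, converged, max deviation) are appended to `meta$raking`.
#' @export
rake_weights <- function(ds, margins, total = NULL, tol = 1e-8,
                         max_iter = 100) {
  stopifnot(inherits(ds, "survey_dataset"), tol > 0, max_iter >= 1)
  d <- ds$data
  w <- d[[ds$weight_col]]
  if (is.null(total)) total <- sum(w)
  for (cv in names(margins)) {
    if (!cv %in% names(d)) fail("margin covariate '%s' not in sample", cv)
    tgt <- margins[[cv]]
    if (abs(sum(tgt) - 1) > 1e-9) fail("margin '%s' shares do not sum to 1", cv)
    present <- unique(as.character(d[[cv]]))
    absent <- setdiff(names(tgt)[tgt > 0], present)
    if (length(absent) > 0) {
      fail("raking cannot converge: sample has no respondents in cell %s = %s",
           cv, paste(absent, collapse = ", "))
    }
    extra <- setdiff(present, names(tgt)[tgt > 0])
    if (length(extra) > 0) {
      fail("sample cell %s = %s has zero or missing target share; weights must stay positive",
           cv, paste(extra, collapse = ", "))
    }
  }
  max_dev <- function(w) {
    devs <- vapply(names(margins), function(cv) {
      sh <- tapply(w, as.character(d[[cv]]), sum) / sum(w)
      tgt <- margins[[cv]]
      max(abs(sh[names(tgt)] - tgt), na.rm = TRUE)
    }, numeric(1))
    max(devs, abs(sum(w) - total) / total)
  }
  it <- 0L
  converged <- max_dev(w) <= tol
  while (!converged && it < max_iter) {
    it <- it + 1L
    for (cv in names(margins)) {
      tgt <- margins[[cv]]
      cat_tot <- tapply(w, as.character(d[[cv]]), sum)
      fac <- (tgt * total) / cat_tot[names(tgt)]
      w <- w * fac[as.character(d[[cv]])]
    }
    converged <- max_dev(w) <= tol
  }
  if (!converged) {
    warning(sprintf("raking did not converge in %d passes (max deviation %.2e)",
                    max_iter, max_dev(w)))
  }
  d[[ds$weight_col]] <- as.numeric(w)
  ds$data <- d
  ds$meta$raking <- list(iterations = it, converged = converged,
                         max_deviation = max_dev(w), tol = tol,
                         margins = names(margins), total = total)
  ds
}
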