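# Survey-weighted logistic regression. Coefficients solve the weighted score
# equations sum_i w_i x_i (y_i - pi_i(beta)) = 0 by iteratively reweighted
# least squares; the covariance is the linearized sandwich with per-PSU
# score totals under the same ultimate-cluster rule as the prevalence
# variance. Multicollinearity is screened with generalized variance-inflation
# factors; average marginal effects come from counterfactual predictions
# with delta-method standard errors.

#' Reference levels used for the analytic covariates
#'
#' Reference categories for the modeling dictionary: youngest age group,
#' male, married, every-day cigarette use, lowest income band, no past-week
#' employment, private insurance, non-Hispanic White, and "no" for every
#' binary flag. Applied by [fit_weighted_logit()] before building the design
#' matrix and logged in the fit.
#' @return named character vector level-per-covariate.
#' @export
default_reference_levels <- function() {
  c(age_group = "18-25", sex = "male", marital = "married",
    cigarette3 = "every day", income = "<$50,000", employment = "none",
    insurance = "private", race4 = "non-Hispanic White",
    education = "college graduate", health = "excellent",
    cannabis = "no", stimulant = "no", benzodiazepine = "no",
    heavy_alcohol = "no", moud = "no", hospitalization = "no")
}

build_design <- function(data, formula, reference_levels) {
  mf_vars <- all.vars(formula)
  for (v in mf_vars[-1]) {
    if (!v %in% names(data)) fail("model covariate '%s' not in data", v)
    x <- data[[v]]
    ref <- if (v %in% names(reference_levels)) reference_levels[[v]] else NULL
    if (is.factor(x)) {
      # existing factor order is respected unless a reference is stated
      if (!is.null(ref) && ref %in% levels(x)) {
        data[[v]] <- stats::relevel(x, ref)
      }
    } else if (is.character(x)) {
      lv <- sort(unique(x))
      if (!is.null(ref) && ref %in% lv) lv <- c(ref, setdiff(lv, ref))
      data[[v]] <- factor(x, levels = lv)
    }
  }
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  X <- stats::model.matrix(formula, mf)
  yv <- stats::model.response(mf)
  if (is.logical(yv)) yv <- as.numeric(yv)
  if (is.factor(yv)) yv <- as.numeric(yv) - 1
  if (!all(yv %in% c(0, 1))) fail("outcome must be binary")
  list(X = X, y = yv, data = data)
}

#' Fit a survey-weighted logistic regression
#'
#' @param ds a harmonized [survey_dataset()].
#' @param formula model formula, e.g.
#'   `either_py ~ age_group + sex + stimulant`.
#' @param reference_levels named vector of reference categories (see
#'   [default_reference_levels()]).
#' @param max_iter,score_tol,deviance_tol IRLS controls: convergence when the
#'   maximum absolute score falls below `score_tol` or the relative deviance
#'   change below `deviance_tol`.
#' @param level CI level for the adjusted odds ratios.
#' @param vif_cutoff covariates whose generalized VIF exceeds this value are
#'   flagged (conventional screening cutoff 5).
#' @return object of class `svy_logit`: terms, beta, cov (design-based
#'   sandwich), aor table, vif table, convergence diagnostics, reference
#'   levels, n_used.
#' @export
fit_weighted_logit <- function(ds, formula,
                               reference_levels = default_reference_levels(),
                               max_iter = 100, score_tol = 1e-8,
                               deviance_tol = 1e-10, level = 0.95,
                               vif_cutoff = 5) {
  stopifnot(inherits(ds, "survey_dataset"))
  bd <- build_design(ds$data, formula, reference_levels)
  X <- bd$X; y <- bd$y
  w <- ds_weights(ds)
  w_mean <- w / mean(w)  # scale-invariant: only relative weights matter
  p0 <- wmean(y, w)
  beta <- c(logit(min(max(p0, 1e-6), 1 - 1e-6)), rep(0, ncol(X) - 1))
  names(beta) <- colnames(X)
  deviance_of <- function(b) {
    p <- pmin(pmax(inv_logit(drop(X %*% b)), 1e-12), 1 - 1e-12)
    -2 * sum(w_mean * (y * log(p) + (1 - y) * log(1 - p)))
  }
  dev_old <- deviance_of(beta)
  converged <- FALSE
  it <- 0
  col_sd <- apply(X, 2, stats::sd); col_sd[col_sd == 0] <- 1
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    pi_ <- inv_logit(eta)
    score <- drop(crossprod(X, w_mean * (y - pi_)))
    v <- pmax(pi_ * (1 - pi_), 1e-12)
    H <- crossprod(X, X * (w_mean * v))
    step <- tryCatch(solve(H, score), error = function(e) {
      fail("singular weighted information matrix; check for aliased columns")
    })
    # step-halving keeps Newton stable when a fitted cell saturates
    dev <- deviance_of(beta + step)
    halvings <- 0
    while (dev > dev_old + 1e-10 && halvings < 30) {
      step <- step / 2
      dev <- deviance_of(beta + step)
      halvings <- halvings + 1
    }
    beta <- beta + step
    if (any(abs(beta * col_sd) > 15 & abs(beta) > 15)) {
      fail("separation detected: |beta| diverging on '%s'",
           names(beta)[which.max(abs(beta * col_sd))])
    }
    pi_ <- inv_logit(drop(X %*% beta))
    score <- drop(crossprod(X, w_mean * (y - pi_)))
    if (max(abs(score)) < score_tol ||
        abs(dev - dev_old) < deviance_tol * (abs(dev_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  if (!converged) {
    fail("IRLS did not converge in %d iterations (last max|score| = %.3e)",
         max_iter, max(abs(score)))
  }
  # sandwich covariance: bread = inverse weighted information (on the
  # original weight scale), meat = ultimate-cluster variance of score totals
  pi_ <- inv_logit(drop(X %*% beta))
  v <- pi_ * (1 - pi_)
  A <- crossprod(X, X * (w * v))
  U <- X * (w * (y - pi_))
  Bmat <- ultimate_cluster_var(ds, U)
  Ainv <- solve(A)
  cov <- Ainv %*% Bmat %*% Ainv
  dimnames(cov) <- list(colnames(X), colnames(X))
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(diag(cov))
  aor <- data.frame(term = colnames(X), beta = unname(beta),
                    se = unname(se), aor = exp(unname(beta)),
                    ci_low = exp(unname(beta - z * se)),
                    ci_high = exp(unname(beta + z * se)),
                    stringsAsFactors = FALSE)
  vif <- compute_vif_matrix(X, w, formula)
  vif$flagged <- vif$gvif > vif_cutoff
  refs <- reference_levels[intersect(names(reference_levels),
                                     all.vars(formula)[-1])]
  structure(list(formula = formula, terms = colnames(X), beta = beta,
                 cov = cov, aor = aor, vif = vif, converged = converged,
                 iterations = it, n_used = nrow(X),
                 reference_levels = refs, level = level,
                 design_kind = ds$kind,
                 X = X, y = y, w = w, data = bd$data,
                 ci_convention = "normal (z) Wald on the log-odds scale"),
            class = "svy_logit")
}

#' @export
print.svy_logit <- function(x, ...) {
  cat(sprintf("<svy_logit: %s, n = %d, %d iterations%s>\n", x$design_kind,
              x$n_used, x$iterations,
              if (x$converged) "" else ", NOT converged"))
  print(x$aor[, c("term", "aor", "ci_low", "ci_high")], digits = 3)
  if (any(x$vif$flagged)) {
    cat("VIF > cutoff for:", paste(x$vif$covariate[x$vif$flagged],
                                   collapse = ", "), "\n")
  }
  invisible(x)
}

# Generalized VIF (Fox & Monette) per covariate on the weighted design
# matrix: GVIF_j = det(R_jj) det(R_(-j)) / det(R), with R the weighted
# correlation matrix of the non-intercept columns. For a one-column
# covariate this is the classic 1 / (1 - R^2).
compute_vif_matrix <- function(X, w, formula) {
  Xc <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  if (ncol(Xc) == 0) {
    return(data.frame(covariate = character(0), gvif = numeric(0),
                      df = integer(0)))
  }
  assign_ <- attr(X, "assign")[match(colnames(Xc), colnames(X))]
  labs <- attr(stats::terms(formula), "term.labels")
  wm <- w / sum(w)
  mu <- colSums(Xc * wm)
  Xd <- sweep(Xc, 2, mu)
  S <- crossprod(Xd * sqrt(wm), Xd * sqrt(wm)) / 1  # weighted covariance
  s <- sqrt(diag(S))
  if (any(s == 0)) {
    fail("constant column '%s' in the design matrix",
         colnames(Xc)[s == 0][1])
  }
  R <- S / tcrossprod(s)
  dR <- det(R)
  if (dR < 1e-12) {
    # identify aliased columns via QR
    qr_ <- qr(Xc)
    aliased <- colnames(Xc)[qr_$pivot[-seq_len(qr_$rank)]]
    fail("rank-deficient design matrix; aliased column(s): %s",
         paste(aliased, collapse = ", "))
  }
  out <- lapply(unique(assign_), function(a) {
    j <- which(assign_ == a)
    g <- det(R[j, j, drop = FALSE]) * det(R[-j, -j, drop = FALSE]) / dR
    data.frame(covariate = labs[a], gvif = g, df = length(j),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Generalized variance-inflation factors for a model formula
#'
#' @inheritParams fit_weighted_logit
#' @return data.frame with covariate, gvif, df; values of 1 mean orthogonal
#'   predictors, values above the conventional cutoff of 5 signal
#'   problematic collinearity.
#' @export
compute_vif <- function(ds, formula,
                        reference_levels = default_reference_levels()) {
  bd <- build_design(ds$data, formula, reference_levels)
  compute_vif_matrix(bd$X, ds_weights(ds), formula)
}

#' Average marginal effects for every non-reference level
#'
#' For each categorical covariate X in the model and each non-reference
#' level l, every record is counterfactually set to X = l and to X = ref,
#' predicted probabilities are formed under the fitted model, and the AME is
#' the weighted mean of their difference. Standard errors are by the delta
#' method through the same weighted average; intervals are normal.
#'
#' @param model a fitted [fit_weighted_logit()] object.
#' @param level CI level.
#' @return data.frame: covariate, level (vs. the logged reference), ame, se,
#'   ci_low, ci_high.
#' @export
average_marginal_effects <- function(model, level = 0.95) {
  stopifnot(inherits(model, "svy_logit"))
  if (!model$converged) fail("model did not converge")
  data <- model$data
  w <- model$w
  beta <- model$beta
  z <- stats::qnorm(1 - (1 - level) / 2)
  covs <- all.vars(model$formula)[-1]
  rows <- list()
  for (cv in covs) {
    x <- data[[cv]]
    if (!is.factor(x)) next
    lv <- levels(x)
    ref <- lv[1]
    for (l in setdiff(lv, ref)) {
      pr <- counterfactual_pred(model, data, cv, l)
      p0 <- counterfactual_pred(model, data, cv, ref)
      ame <- sum(w * (pr$p - p0$p)) / sum(w)
      grad <- colSums(w * (pr$p * (1 - pr$p) * pr$X -
                             p0$p * (1 - p0$p) * p0$X)) / sum(w)
      se <- sqrt(drop(t(grad) %*% model$cov %*% grad))
      rows[[length(rows) + 1]] <- data.frame(
        covariate = cv, level = l, reference = ref,
        ame = ame, se = se, ci_low = ame - z * se, ci_high = ame + z * se,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

counterfactual_pred <- function(model, data, covariate, lev) {
  if (!lev %in% levels(data[[covariate]])) {
    fail("level '%s' absent from model covariate '%s'", lev, covariate)
  }
  d <- data
  d[[covariate]] <- factor(rep(lev, nrow(d)),
                           levels = levels(data[[covariate]]))
  X <- stats::model.matrix(model$formula, stats::model.frame(
    model$formula, d, na.action = stats::na.fail))
  p <- inv_logit(drop(X %*% model$beta))
  list(p = p, X = X)
}
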