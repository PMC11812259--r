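# Helper: plain panel dataset with factor covariates for model fitting.
logit_panel <- function(n, beta0 = -1, beta1 = 0.8, seed = 1,
                        w = rep(1, n)) {
  set.seed(seed)
  x <- factor(sample(c("no", "yes"), n, TRUE), levels = c("no", "yes"))
  eta <- beta0 + beta1 * (x == "yes")
  y <- runif(n) < 1 / (1 + exp(-eta))
  survey_dataset(data.frame(respondent_id = seq_len(n), y = y, x = x,
                            weight = w),
                 kind = "optin_panel")
}

test_that("intercept-only fit recovers the logit of the weighted prevalence", {
  set.seed(11)
  n <- 500
  ds <- logit_panel(n, w = runif(n, 0.5, 3))
  fit <- fit_weighted_logit(ds, y ~ 1)
  p <- sum(ds$data$weight * ds$data$y) / sum(ds$data$weight)
  expect_equal(unname(fit$beta[1]), log(p / (1 - p)), tolerance = 1e-10)
  expect_true(fit$converged)
})

test_that("single binary predictor matches the weighted 2x2 closed form", {
  set.seed(12)
  n <- 600
  ds <- logit_panel(n, w = runif(n, 0.5, 3))
  d <- ds$data
  a <- sum(d$weight[d$x == "yes" & d$y])      # exposed cases
  b <- sum(d$weight[d$x == "yes" & !d$y])
  c_ <- sum(d$weight[d$x == "no" & d$y])
  dd <- sum(d$weight[d$x == "no" & !d$y])
  fit <- fit_weighted_logit(ds, y ~ x)
  expect_equal(unname(fit$beta["xyes"]), log((a * dd) / (b * c_)),
               tolerance = 1e-8)
  expect_equal(unname(fit$aor$aor[fit$aor$term == "xyes"]),
               (a * dd) / (b * c_), tolerance = 1e-7)
})

test_that("equal-weight fits equal ordinary maximum-likelihood logistic regression", {
  ds <- logit_panel(800, seed = 13)
  fit <- fit_weighted_logit(ds, y ~ x)
  ml <- glm(y ~ x, family = binomial, data = ds$data)
  expect_equal(unname(fit$beta), unname(coef(ml)), tolerance = 1e-8)
})

test_that("coefficients recover truth within 3 model SEs at n = 5000", {
  ds <- logit_panel(5000, beta0 = -1.2, beta1 = 0.9, seed = 14)
  fit <- fit_weighted_logit(ds, y ~ x)
  se <- sqrt(diag(fit$cov))
  expect_lt(abs(fit$beta["(Intercept)"] + 1.2), 3 * se["(Intercept)"])
  expect_lt(abs(fit$beta["xyes"] - 0.9), 3 * se["xyes"])
})

test_that("beta, VIF and AME are invariant to rescaling all weights", {
  set.seed(15)
  n <- 400
  w <- runif(n, 0.5, 4)
  ds1 <- logit_panel(n, w = w, seed = 16)
  ds2 <- ds1; ds2$data$weight <- w * 11
  f1 <- fit_weighted_logit(ds1, y ~ x)
  f2 <- fit_weighted_logit(ds2, y ~ x)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
  expect_equal(f1$cov, f2$cov, tolerance = 1e-8)
  expect_equal(f1$vif$gvif, f2$vif$gvif, tolerance = 1e-10)
  expect_equal(average_marginal_effects(f1)$ame,
               average_marginal_effects(f2)$ame, tolerance = 1e-10)
})

test_that("design-based covariance uses PSU score totals (clustered vs iid differ)", {
  set.seed(17)
  n <- 300
  stratum <- rep(1:3, each = 100)
  psu <- rep(1:15, each = 20)
  cluster_effect <- rnorm(15, sd = 0.8)[psu]
  x <- factor(sample(c("no", "yes"), n, TRUE), levels = c("no", "yes"))
  y <- runif(n) < 1 / (1 + exp(-(-0.5 + 0.6 * (x == "yes") + cluster_effect)))
  dcl <- survey_dataset(
    data.frame(respondent_id = 1:n, stratum = stratum, psu = psu,
               y = y, x = x, weight = rep(1, n)),
    kind = "probability_clustered", stratum_col = "stratum", psu_col = "psu")
  dfl <- survey_dataset(
    data.frame(respondent_id = 1:n, y = y, x = x, weight = rep(1, n)),
    kind = "optin_panel")
  fc <- fit_weighted_logit(dcl, y ~ x)
  ff <- fit_weighted_logit(dfl, y ~ x)
  expect_equal(fc$beta, ff$beta, tolerance = 1e-9)  # same point estimates
  # positive intra-cluster correlation inflates the clustered SE
  expect_gt(sqrt(fc$cov["(Intercept)", "(Intercept)"]),
            sqrt(ff$cov["(Intercept)", "(Intercept)"]))
})

test_that("VIF is 1 for orthogonal predictors and 1/(1-R^2) for correlated ones", {
  # balanced orthogonal factors
  g <- expand.grid(x = c("no", "yes"), z = c("no", "yes"))
  d <- g[rep(1:4, each = 25), ]
  set.seed(18)
  d$y <- runif(100) < 0.4
  d$weight <- 1
  ds <- survey_dataset(cbind(respondent_id = 1:100, d), kind = "optin_panel")
  v <- compute_vif(ds, y ~ x + z)
  expect_equal(v$gvif, c(1, 1), tolerance = 1e-10)
  # two continuous predictors with correlation 0.9 -> VIF ~ 1/(1-0.81)
  set.seed(19)
  n <- 10000
  a <- rnorm(n)
  b <- 0.9 * a + sqrt(1 - 0.81) * rnorm(n)
  dd <- data.frame(respondent_id = 1:n, y = runif(n) < 0.3, a = a, b = b,
                   weight = 1)
  ds2 <- survey_dataset(dd, kind = "optin_panel")
  v2 <- compute_vif(ds2, y ~ a + b)
  expect_equal(v2$gvif, rep(1 / (1 - 0.81), 2), tolerance = 0.02 * 5.26)
  # duplicated column is a named rank-deficiency error
  dd$b2 <- dd$b
  ds3 <- survey_dataset(dd, kind = "optin_panel")
  expect_error(compute_vif(ds3, y ~ b + b2), "rank-deficient|aliased")
})

test_that("separation raises an explicit error rather than silently diverging", {
  d <- data.frame(respondent_id = 1:40,
                  x = factor(rep(c("no", "yes"), each = 20),
                             levels = c("no", "yes")),
                  y = rep(c(FALSE, TRUE), each = 20),
                  weight = 1)
  ds <- survey_dataset(d, kind = "optin_panel")
  expect_error(fit_weighted_logit(ds, y ~ x), "separation|singular")
})

test_that("AME is 0 for null coefficients and equals group-prevalence gaps when saturated", {
  # force a zero coefficient by construction: y independent of x, fit on a
  # huge weight of evidence -> use the saturated identity instead
  set.seed(20)
  n <- 800
  w <- runif(n, 0.5, 2)
  ds <- logit_panel(n, beta0 = -0.7, beta1 = 1.1, seed = 21, w = w)
  fit <- fit_weighted_logit(ds, y ~ x)
  ame <- average_marginal_effects(fit)
  d <- ds$data
  p_yes <- sum(d$weight[d$x == "yes"] * d$y[d$x == "yes"]) /
    sum(d$weight[d$x == "yes"])
  p_no <- sum(d$weight[d$x == "no"] * d$y[d$x == "no"]) /
    sum(d$weight[d$x == "no"])
  expect_equal(ame$ame, p_yes - p_no, tolerance = 1e-8)
  # a literally zero coefficient gives exactly zero AME
  fit0 <- fit
  fit0$beta["xyes"] <- 0
  ame0 <- average_marginal_effects(fit0)
  expect_equal(ame0$ame, 0)
})

test_that("AME matches a brute-force record-by-record counterfactual loop", {
  set.seed(22)
  n <- 300
  d <- data.frame(
    respondent_id = 1:n,
    x = factor(sample(c("lo", "mid", "hi"), n, TRUE),
               levels = c("lo", "mid", "hi")),
    z = factor(sample(c("no", "yes"), n, TRUE), levels = c("no", "yes")),
    weight = runif(n, 0.5, 3))
  eta <- -0.8 + 0.7 * (d$x == "mid") + 1.2 * (d$x == "hi") + 0.5 * (d$z == "yes")
  d$y <- runif(n) < 1 / (1 + exp(-eta))
  ds <- survey_dataset(d, kind = "optin_panel")
  fit <- fit_weighted_logit(ds, y ~ x + z)
  ame <- average_marginal_effects(fit)
  # oracle: loop over records, set x to the level and to the reference,
  # compute predicted probabilities from the coefficients by hand, average
  b <- fit$beta
  pred <- function(xlev, zval) {
    eta <- b["(Intercept)"] + b["xmid"] * (xlev == "mid") +
      b["xhi"] * (xlev == "hi") + b["zyes"] * (zval == "yes")
    1 / (1 + exp(-unname(eta)))
  }
  for (lev in c("mid", "hi")) {
    tot <- 0
    for (i in seq_len(n)) {
      tot <- tot + d$weight[i] * (pred(lev, d$z[i]) - pred("lo", d$z[i]))
    }
    expect_equal(ame$ame[ame$covariate == "x" & ame$level == lev],
                 tot / sum(d$weight), tolerance = 1e-10)
  }
  expect_error(dualsurvey:::counterfactual_pred(fit, fit$data, "x", "huge"),
               "absent")
  expect_true(all(ame$ame >= -1 & ame$ame <= 1))
})

test_that("aOR table is consistent: aor = exp(beta), positive CI bounds, symmetric PSD covariance", {
  ds <- logit_panel(500, seed = 23, w = runif(500, 0.5, 2))
  fit <- fit_weighted_logit(ds, y ~ x)
  expect_equal(fit$aor$aor, exp(fit$aor$beta), tolerance = 1e-12)
  expect_true(all(fit$aor$ci_low > 0))
  expect_true(all(fit$aor$ci_low <= fit$aor$aor & fit$aor$aor <= fit$aor$ci_high))
  expect_equal(fit$cov, t(fit$cov), tolerance = 1e-12)
  ev <- eigen(fit$cov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-12))
})
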