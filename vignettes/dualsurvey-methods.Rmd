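---
title: "Cross-survey prevalence comparison: models, estimators and calibration"
author: "dualsurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-survey prevalence comparison: models, estimators and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualsurvey)
```

## The problem

National surveillance of heroin and illicitly manufactured fentanyl (IMF)
use rests on surveys with very different sampling machinery. A
probability-based household survey recruits by address within a stratified
multi-stage cluster design and weights respondents by inverse inclusion
probability with nonresponse adjustment; an opt-in web panel recruits
volunteers, so its analytic weights come from calibration (raking) to known
population margins rather than from a sampling design. Because the two
designs cannot be pooled into one model, comparing their prevalence
estimates needs a procedure that treats each survey on its own terms.
`dualsurvey` implements that procedure end to end — design-based prevalence
estimation, a replicate-resampling bootstrap for cross-survey differences
with Bonferroni-corrected percentile intervals, and survey-weighted logistic
regression with average marginal effects — together with a synthetic
dual-survey generator whose population truth is known exactly, so every
estimator can be scored against truth without access to restricted survey
microdata.

## Outcome harmonization

Both emulated instruments ask a past-year and a past-month use item per
substance. `classify_recency()` maps the pair to an ordered three-level
recency (`none < months_2_12 < past_month`); a past-month report without
past-year use is rejected as a data inconsistency rather than repaired.
The combined "either heroin or IMF" outcome is the elementwise maximum
under that order (`derive_either()`): a person is counted at their most
recent exposure to either substance, reflecting that respondents often
cannot distinguish IMF in a heroin supply. Further shared rules: heavy
alcohol use is at least 15 drinks/week for men and 8 for women (inclusive
thresholds); sparse race/ethnicity categories collapse into a single
"another non-Hispanic race" group for modeling; blank cigarette items are
analyzed as "not at all". Harmonization never drops records and never
touches weights.

## Design-based estimation

The prevalence estimator is the weighted ratio
$\hat p = \sum_i w_i y_i / \sum_i w_i$. Its variance is Taylor-linearized
under the ultimate-cluster, with-replacement approximation: with score
residuals $u_i = w_i (y_i - \hat p)$ totalled per PSU into $z_{hj}$,

$$\widehat{\mathrm{Var}}(\hat p) \;=\;
  \frac{1}{(\sum_i w_i)^2}\sum_h \frac{n_h}{n_h-1}
  \sum_j \left(z_{hj}-\bar z_h\right)^2 ,$$

the de facto standard for national household-survey designs. The opt-in
panel is treated as a single-stage design with each respondent its own
sampling unit. Three numerical conventions matter:

* **No finite-population correction.** First-stage clusters are treated as
  drawn with replacement. A consequence worth stating plainly: on a census
  the estimator does not return zero variance; removing that approximation
  is out of scope, and the estimator's calibration is instead demonstrated
  by simulation (95% CIs cover the realized population prevalence within
  ±3 points over 500 replicate clustered draws, in the test suite).
* **Singleton-PSU strata are an error**, never silently collapsed — the
  analyst must redesign, not the software.
* **Logit-transformed intervals.** At prevalences near 0.5% a symmetric
  Wald interval can cross zero; the normal interval is therefore built on
  the log-odds with delta-method SE $\mathrm{se}/(\hat p(1-\hat p))$ and
  back-transformed. Exact 0 or 1 estimates collapse to a flagged point
  interval. The interval method is recorded in every output row.

## The cross-survey bootstrap

Each survey is resampled with replacement `B = 2000` times (the reference
replicate count): the probability survey by PSUs within strata — the unit
its variance estimator assumes — and the panel by respondents. The unit is
a logged switch (`psu` / `respondent`), weights are carried into replicates
unmodified (per-replicate re-raking is deliberately off by default; it is a
config option), and replicate `b` of each survey draws from the child-seed
streams `child_seed(seed, b, "A"/"B")`, so the whole distribution is
reproducible bit for bit. The reported point difference is the mean of the
replicate differences, signed as panel minus probability survey; the plain
difference of the original point estimates is also emitted.

Intervals are empirical percentile intervals using the linearly interpolated
inverse empirical CDF (R's quantile type 4). The tail behaviour of this rule
matters: Bonferroni correction pushes interval levels to extremes (for a
43-comparison family at family-wise $\alpha = 0.05$, the per-comparison
level is $0.05/43 = 0.0012$, i.e. 99.88% intervals), where type 4 reaches
the extreme order statistics sooner than R's default type-7 rule and is
accordingly less anti-conservative at small `B`. Corrected intervals always
contain the uncorrected ones (asserted on every run). Replicates on which an
estimator fails are excluded and counted; more than 5% exclusions aborts the
analysis.

## Survey-weighted logistic regression

Coefficients solve the weighted score equations
$\sum_i w_i x_i (y_i - \pi_i(\beta)) = 0$ by iteratively reweighted least
squares with step-halving (convergence at max |score| < 1e−8 or relative
deviance change < 1e−10, at most 100 iterations). The covariance is the
linearized sandwich $A^{-1} B A^{-1}$ with $A$ the weighted information and
$B$ the same ultimate-cluster variance applied to per-PSU score totals.
Adjusted odds ratios use normal (z) Wald intervals on the log-odds scale —
the degrees-of-freedom convention is recorded in the fit object.
Separation is an explicit error (divergence monitored on standardized
coefficients): sparse cells are the analyst's signal to collapse
categories, which is exactly how the sparse race groups came to be
combined. Multicollinearity is screened with generalized VIFs (Fox–Monette)
on the weighted design matrix, flagged above the conventional cutoff of 5.
Reference levels are fixed and logged: age 18–25, male, married, every-day
cigarette use, income < \$50,000, no past-week employment, private
insurance, non-Hispanic White, and "no" for the binary flags.

Average marginal effects set every record counterfactually to each
non-reference level and to the reference, average the difference in
predicted probability with the analytic weights, and propagate uncertainty
by the delta method (chosen over a bootstrap SE for determinism; a
bootstrap option can reuse the resampler).

## The synthetic dual-survey generator

The generator defines the study conditions; it is deliberately simple and
fully inspectable:

* **Population.** Categorical covariates drawn from stated margins
  (independent by default, with an optional pairwise log-odds tilt so that,
  e.g., stimulant and benzodiazepine use correlate — OR $e^{1.5}$ in the
  shipped defaults). Past-year heroin and IMF use are Bernoulli draws from
  per-outcome logistic models; recency among past-year users is a single
  two-level split (past-month probability 0.65 for heroin, 0.45 for IMF).
  The "4 weeks" vs "30 days" wording difference between real instruments is
  modeled as one past-month construct (misclassification knob defaulting
  to 0).
* **Probability survey.** Balanced random partition into strata and PSUs,
  SRSWOR at both stages, inverse-inclusion base weights, logistic
  nonresponse (employed persons respond less in the defaults) with
  inverse-response-rate weight adjustment within covariate classes.
* **Opt-in panel.** Independent logistic self-selection over-recruiting
  college graduates, non-Hispanic White respondents, smokers and people who
  use stimulants or benzodiazepines; two pooled waves; uniform initial
  weights raked by iterative proportional fitting to the population margins
  of age, sex, race, education and income (tolerance 1e−8 on every margin
  share and on the weight total).

The shipped default configuration was calibrated once, by exhaustive
enumeration over the covariate cells of the outcome models, so that
population either-use prevalence is ≈ 0.48% and the selection-weighted
panel prevalence ≈ 1.0% — the half-percent-versus-one-percent regime in
which national heroin/IMF surveillance operates. The panel's residual
inflation after raking is the designed behaviour: its selection acts on
substance-use covariates that raking (demographics only) cannot repair.
All effect sizes are illustrative: the real surveys publish no generative
model, so parameter values are the package's own choices, labeled as such.

What the generator does **not** emulate: questionnaire mode and ordering
effects, multi-stage nonresponse weighting of real household surveys, panel
attrition/economics, item nonresponse beyond the cigarette blank, and
measurement error in self-report. Passing tests therefore demonstrate that
the estimators are correct and calibrated under a known truth — not that
any particular real-survey discrepancy is causally explained.

## Calibration studies

Three experiments (exported functions, run by `analysis/05_calibration.R`,
the test suite and the acceptance script) score the machinery at stated
sizes, chosen as desk-scale stand-ins for the production analysis:

1. **Null family-wise error** — 200 families, two n = 5000 surveys from one
   population, m = 10 equal-prevalence outcomes, B = 500: the share of
   families where any corrected interval excludes zero should stay at the
   family-wise α up to Monte-Carlo error. The probability survey in each
   family carries 5 strata × 40 PSUs: cluster counts large enough that the
   uncorrected with-replacement bootstrap's $(n_h-1)/n_h$ variance
   deflation is negligible (Rao–Wu rescaling is out of scope). Residual
   excess over α reflects bootstrap-quantile noise at the extreme corrected
   level (an inherent property of percentile intervals at B = 500, visible
   in an idealized normal model as well).
2. **Difference recovery** — 200 experiments with true prevalences 0.5% vs
   1.0% (a 0.5-percentage-point difference at surveillance scale), n = 5000,
   B = 1000, m = 10: corrected-interval coverage at its nominal 99.5% level
   and unbiasedness of the bootstrap-mean point difference within 3
   Monte-Carlo SEs.
3. **Regression coverage** — 300 replicates at n = 800 with a binary
   predictor (true slope 0.8): 95% Wald coverage within ±3.5 points, and
   equal-weight fits agreeing with ordinary ML logistic regression to 1e−8.

Monte-Carlo standard errors are computed from the observed rates (the
standard simulation-study convention). No empirical number appears in this
vignette that the tests or the acceptance script do not themselves compute.

## Determinism and seeds

Every random draw flows from one master seed through `child_seed()`, a
31-bit labeled-stream hash; stages (population, each survey, each bootstrap
replicate) use disjoint labeled streams. Rerunning `run_pipeline()` with the
same configuration reproduces byte-identical CSVs, which the test suite
asserts file by file.

## Known limitations

* Percentile intervals (not BCa/studentized); at Bonferroni-extreme levels
  they are slightly anti-conservative for small B — use B ≥ 2000 for
  production families, as the reference analysis does.
* No Rao–Wu rescaling: designs with very few PSUs per stratum will see
  modest bootstrap variance deflation.
* The opt-in panel is modeled with single-stage self-selection and
  demographic-margin raking only; real panel weighting is richer.
* Whether the emulated production analysis resampled respondents or PSUs is
  not documented; both modes are implemented, the defaults are this
  package's choice and are stamped into every output manifest.
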