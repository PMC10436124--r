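---
title: "Methods: joint hazards of correlated air-pollutant exposures"
author: "airmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint hazards of correlated air-pollutant exposures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airmix)
```

## The problem

Long-term exposure to fine particulate matter (PM2.5) and ozone (as the
annual mean of the daily 8-hour maximum, MDA8 O3) has been linked to incident
asthmatic symptoms in ageing cohorts. Because the two pollutants are strongly
correlated in ambient air (Pearson r around 0.66 in Chinese cohort data),
single-pollutant effect estimates overlap, and the public-health question —
how much disease burden does the *mixture* cause — needs a joint model.
`airmix` implements the full estimation chain for this setting:

1. a counting-process Cox proportional-hazards engine for time-varying annual
   exposures,
2. per-quartile hazard ratios and natural-spline exposure–response curves,
3. quantile g-computation with a Cox underlying model for the mixture index
   effect and component weights,
4. Levin-type population-attributable fractions (PAFs) with Monte-Carlo
   confidence intervals, and
5. subgroup analyses with two-sample z heterogeneity tests and Bonferroni
   correction,

together with a calibrated synthetic-cohort generator, so every estimator can
be validated by simulation against a known truth.

## Data model

The unit of analysis is the person-period record: subject, interval
`(start, stop]` in years on study, a 0/1 event indicator attached to `stop`,
the annual exposure means in force during the interval, and categorical
covariates. A subject followed 6.4 years contributes 7 records (six whole
years and a 0.4-year remainder); the annual exposures change at calendar-year
boundaries, which is what makes the exposure time-varying. A subject is at
risk at time `t` when `start < t <= stop`; censoring exactly at a year
boundary produces no zero-length record. Complete cases are required: any
missing exposure or covariate value is an error at validation time, mirroring
the exclusion of subjects with missing key covariates in the cohorts this
package targets.

### Quartile coding

Each pollutant is coded 0–3 against its 25th/50th/75th percentiles. Two
choices are deliberately pinned because published analyses rarely state them:

* **Percentile basis.** Percentiles are computed over *person-period
  records*, not subjects, because the fitted covariate is the record-level
  annual mean. (A subject-baseline basis can be emulated by passing a fixed
  `quantile_spec`.)
* **Boundary rule.** Bins are right-closed (`x <= q25` is category 0, values
  exactly at a cut point fall in the lower category) and percentiles use the
  type-7 linear-interpolation convention. Any consistent rule would do; one
  is fixed for reproducibility.

## The Cox engine

The partial likelihood for counting-process data is maximized by
Newton–Raphson with analytic gradient and Hessian, implemented in C++ as a
single ascending sweep over distinct event times that maintains the risk-set
sums \(S_0=\sum_R w_i\), \(S_1=\sum_R w_i x_i\), \(S_2=\sum_R w_i x_i
x_i^\top\) incrementally (records are added when their entry time passes and
subtracted when their exit time passes), so one evaluation costs
\(O(n\log n + n p^2)\). Both Efron (default) and Breslow corrections for
tied event times are available; without ties they coincide exactly. The
linear predictor is centred before exponentiation, which cancels identically
in every term of the likelihood and keeps the weights finite.

Numerical choices: convergence requires the score max-norm below `tol`
(default 1e-8) or a relative log-likelihood change below 1e-10; steps are
halved when the log-likelihood would decrease; a coefficient norm above 15 on
the log scale sets a monotone-likelihood flag and raises a warning; the
covariance is the inverse observed information at the optimum, and a singular
information matrix is an error naming the design column that dominates the
null space. The engine is validated against direct risk-set enumeration (to
1e-10) and against `survival::coxph` (to 1e-5, with `timefix` disabled so
both sides see the same tie structure).

Per-quartile hazard ratios enter the model as the numeric 0–3 score with a
single coefficient, so "HR per quartile increment" is `exp(beta)`.
Stratification is not used; subgroup estimates come from subset refits.

### Splines

Nonlinearity is explored with a natural cubic spline with 3 degrees of
freedom. The knots are pinned: interior knots at the 33.3rd/66.7th exposure
percentiles, boundary knots at the 1st/99th. The curve is reported as the
log-HR difference from a reference exposure (default: the median), with
delta-method pointwise bands; it is exactly zero with zero-width CI at the
reference. The basis (`splines::ns`) is tested to span the same space as an
independently built truncated-power natural-spline basis.

## Quantile g-computation

With every mixture member quartile-coded and entered jointly (plus
covariates), a simultaneous one-quantile increase in all members changes the
log hazard by \(\psi = \sum_j \beta_j\). Because the specification is linear
with no interactions, \(\psi\) and the weights come directly from the fitted
coefficients (the "noboot" analogue); the bootstrap marginal-structural
variant for nonlinear mixtures is out of scope. The variance is
\(\operatorname{var}(\psi) = \mathbf{1}^\top \Sigma \mathbf{1}\) from the
coefficient covariance, giving a Wald interval for the joint HR
\(e^\psi\). Weights follow the standard sign convention: with a common sign
\(w_j=\beta_j/\psi\) and \(\sum w_j = 1\); with mixed signs the positive and
negative directions are normalized separately and the weights total 2.
Ambient temperature is an adjustment covariate, not a mixture member.

## Population-attributable fractions

The multicategory Levin form
\[
\mathrm{PAF} = \frac{\sum_i p_i (RR_i - 1)}{1 + \sum_i p_i (RR_i - 1)}
\]
is the primitive. Two prevalence models map a fitted per-quartile (or
mixture) log-HR onto categories:

* **single-increment** (default): one exposed category with \(p = 0.25\) at
  \(RR = e^{\hat\beta}\). This is pinned as the operative published usage
  because it reproduces the printed PAFs from the printed HRs to rounding
  (HR 1.18 gives 4.31% against a printed 4.32%; HR 1.1176 gives 2.86%).
* **multicategory**: \(p = 0.25\) in each non-reference quartile \(k\) at
  \(RR = e^{k\hat\beta}\), which gives visibly larger values and does *not*
  match the printed numbers — kept as an explicit alternative.

The joint PAF is the single-increment Levin form applied to the qgcomp
mixture index \(\psi\). The complement-product rule
\(1-\prod_i(1-\mathrm{PAF}_i)\) over the two single-pollutant PAFs is
provided only as a secondary utility: applied to the published individual
PAFs it yields 7.11%, far from the published joint 4.32%, precisely because
it ignores the correlation that the mixture model accounts for.

Uncertainty: coefficient vectors are drawn from
\(N(\hat\beta, \hat\Sigma)\) (10,000 draws by default, seeded), each draw is
mapped through the Levin formula, and the 2.5th/97.5th percentiles of the
draws form the CI. The percentile interval (not bias-corrected) is pinned.
An indefinite covariance is an error, with an optional
clip-negative-eigenvalues repair that is off by default.

## Subgroups and heterogeneity

Within each level of a subgroup variable, the single-pollutant and mixture
models are refitted with the subgroup variable removed from the adjustment
set; quartile cut points stay fixed at their full-cohort values so "per
quartile" means the same contrast in every stratum. Strata without events are
skipped with a warning. Between-stratum differences use
\(z = (b_1-b_2)/\sqrt{SE_1^2+SE_2^2}\) with two-sided normal p values;
within a variable with \(L\) levels the Bonferroni multiplier is the number
of pairwise comparisons \(\binom{L}{2}\), and both raw and adjusted p values
are reported since published tables rarely state which is shown. The
back-calculation of a log-scale SE from a printed 95% CI,
\((\ln U - \ln L)/3.92\), is exposed as a test-and-consistency utility.
Temperature subgrouping uses quartiles of subject-mean temperature.
Collinearity screening uses classical VIFs \(1/(1-R^2_k)\).

## The synthetic-cohort generator

The generator exists so that the whole chain is testable without access to
individual-level cohort data, which are not publicly deposited for the study
population this package emulates. Its defaults are calibrated to that
population's printed summaries, and they are treated as fixed study
conditions, not tuning knobs:

* **Exposures.** A latent Gaussian process per subject with cross-exposure
  correlation \(r(\mathrm{PM2.5},\mathrm{O3})=0.663\),
  \(r(\mathrm{PM2.5},T)=0.090\), \(r(\mathrm{O3},T)=0.428\) at every year
  and AR(1) persistence (coefficient 0.8) across years, mapped through
  normal marginals — PM2.5 mean 42.85 (SD 12.74) μg/m³, O3 mean 94.19
  (SD 5.62) μg/m³, temperature 15.0 (SD 4.5) °C — truncated at zero for the
  concentrations (a closed-form quantile map, so the copula is preserved).
  The AR coefficient is not stated in the source material; 0.8 was chosen
  once to mimic slowly varying annual pollution. The published PM2.5 mean is
  internally inconsistent between the results text (42.85) and the baseline
  table (46.20); both are carried as presets (`pm25_preset`), with the text
  value as default, and no attempt is made to adjudicate.
* **Covariates.** Independent categorical draws at the printed baseline
  margins (age group, sex, urbanicity, region, marital status, BMI class,
  cooking fuel, smoking, drinking, income, education). Dependence between
  covariates can be injected for stress tests but is off by default.
* **Follow-up.** Durations are normal with mean 6.9 and SD 2.3 years,
  truncated to [1, 11], with the location shifted so the *truncated* mean is
  6.9. The printed 58,737 person-years equals 8490 × 6.9, i.e. follow-up to
  last contact: events are ascertained at scheduled interviews and do not
  truncate the printed follow-up. The generator therefore reports both the
  observation window (`followup_years`, which matches n × 6.9) and at-risk
  person-time (`person_years`, about 3% smaller because subjects exit the
  risk set at their event).
* **Events.** Piecewise-exponential within subject-years: the hazard is
  \(\lambda_0 e^{lp}\) with the linear predictor built from the true
  per-quartile log-HRs on the quartile-coded exposures (default components
  0.68 and 0.32 of ln 1.18, matching the published joint effect and weight
  split), per-level covariate log-HRs (age 65+: ln 1.5, urban: ln 1.3,
  ever-smoker: ln 1.2 — chosen once as plausible magnitudes; the source
  does not print covariate coefficients), and optional subgroup multipliers
  on the exposure effects for effect-modification studies. Event times come
  from inverse-transform sampling of the accumulated hazard. With
  `baseline_hazard = "calibrate"`, \(\lambda_0\) solves
  \(\mathbb{E}[\text{incidence}] = 0.069\) in closed form given the drawn
  exposures, covariates and durations (the expected incidence is
  \(\operatorname{mean}(1-e^{-\lambda_0 B_i})\), monotone in
  \(\lambda_0\)). Detection is exact-time by default; the source study
  observed outcomes at interview waves, but its risk-time handling is
  unstated, so the simpler convention is pinned.
* **Exposure response.** The default truth operates on the quartile score,
  matching the analysis model (so recovery tests are well-posed). A
  `"linear"` mode makes the log hazard linear in the raw exposure, used to
  check the spline estimator against a smooth known truth.

What the generator does *not* emulate: spatially explicit exposure fields,
real meteorology, address changes, covariate dependence, interval-censored
outcome ascertainment, or loss to follow-up that is informative of the
outcome. Passing recovery tests therefore demonstrates estimator
correctness under the stated generating model, not robustness to those
real-data complications.

## Validation design and problem sizes

The test suite works at three levels.

* **Oracles.** The partial likelihood is checked against direct risk-set
  enumeration and numerical derivatives; the one-dimensional fit against a
  grid search (absolute 1e-4); the full fitter against
  `survival::coxph` on random small cohorts; the spline basis against a
  truncated-power construction; PAF Monte-Carlo percentiles against the
  closed-form transform of normal quantiles (the 1-D PAF is a monotone map
  of a normal draw).
* **Properties.** Monotone quartile coding with balanced categories;
  person-time and event conservation under expansion; Efron = Breslow
  without ties; likelihood concavity; weight-sum rules (1 or 2); PAF
  monotonicity and zero at RR 1; z-test antisymmetry; Bonferroni dominance;
  95% Wald coverage within [90%, 99%] at n = 2000 over 200 simulations;
  byte-identical reruns under equal seeds.
* **Recovery.** With the generator's truth set to the published estimates,
  the pipeline re-estimates: single-pollutant HRs 1.12 (O3) and 1.18
  (PM2.5) each from 50 cohorts of n = 8490 (each pollutant simulated as the
  sole causal exposure — under a joint truth with r = 0.663 a
  single-pollutant fit is confounded upward by construction, so the
  single-pollutant published values are treated as single-truth designs);
  the joint HR 1.18 and the 68%/32% weight split from 100 cohorts (the
  per-seed weight ratio is heavy-tailed because its denominator \(\psi\) is
  only about 2 SEs from zero in one cohort, so this arm uses more seeds);
  the 6.9% incidence and 0.663 exposure correlation from the default
  calibration; and an obese-stratum joint HR of 2.05 from a planted
  effect-modification multiplier. These sizes keep the whole suite under a
  few minutes on one core while leaving the recovery tolerances at 3 or
  more Monte-Carlo standard errors.

## Known limitations

* Time-varying *coefficients* (as opposed to covariates) are not
  implemented; the published phrase "time-varying covariates and
  coefficients" is read as time-varying covariates with constant
  coefficients, which is what a single reported HR implies.
* The qgcomp variance is the Wald form from the coefficient covariance;
  whether the published analysis used bootstrap variance is unstated.
* Left truncation beyond the start–stop encoding, frailty terms and
  penalized splines are out of scope.
* The Levin PAF treats the hazard ratio as a relative risk, which is
  standard at low incidence (6.9% here) but approximate.
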