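# airmix

Individual and joint hazards of long-term air-pollutant exposure in cohort
studies — time-varying Cox regression, quantile g-computation for the
PM2.5 + ozone mixture, population-attributable fractions with Monte-Carlo
confidence intervals, subgroup heterogeneity testing, and a calibrated
synthetic-cohort generator.

## Who this is for

Environmental epidemiologists analysing prospective cohorts where each
subject carries annual mean exposures (fine particulate matter PM2.5, ozone
MDA8 O3, temperature) that change year to year, and where the question is
both *per-pollutant* ("HR per quartile increment") and *joint* ("what does a
simultaneous one-quantile increase in the whole mixture do, and how much
disease burden does it explain?"). Because PM2.5 and O3 are strongly
correlated (r ≈ 0.66), the package treats the mixture model — not the sum of
single-pollutant models — as the primary joint estimate.

## The models

- **Cox proportional hazards on counting-process data.** Each subject
  contributes `(start, stop]` person-period records; the risk set at event
  time *t* is `{start < t ≤ stop}`. The partial likelihood (Efron or Breslow
  ties) is maximized by Newton–Raphson with analytic derivatives in compiled
  code. Quartile-coded exposure scores (0–3) give HRs per quartile
  increment; a natural spline with 3 df gives exposure–response curves.
- **Quantile g-computation (Cox underlying model).** All mixture exposures
  quartile-coded and entered jointly: the mixture index is ψ = Σβⱼ, the
  joint HR is exp(ψ) with Wald variance 1ᵀΣ1, and component weights are
  βⱼ/ψ (summing to 1 with a common sign, to 2 across directions otherwise).
- **Population-attributable fractions.** Levin's formula
  PAF = Σpᵢ(RRᵢ−1) / (1 + Σpᵢ(RRᵢ−1)), applied by default as a
  single-increment model (exposed proportion 0.25 at the per-quartile HR);
  CIs from 10,000 seeded draws of the coefficients from N(β̂, Σ̂).
- **Subgroups.** Stratum refits (dropping the subgroup variable from the
  adjustment set), two-sample z tests z = (b₁−b₂)/√(SE₁²+SE₂²) for
  heterogeneity, Bonferroni correction over pairwise level comparisons, and
  VIF collinearity screening.
- **Synthetic cohorts.** Gaussian-copula exposures with AR(1) year-to-year
  persistence calibrated to published marginals and correlations, Table-style
  covariate margins, piecewise-exponential events with the baseline hazard
  solved for a target cumulative incidence, and configurable true effects —
  so every estimator is testable against a known truth.

## Worked example

```r
library(airmix)

cohort <- make_cohort(generator_config(), seed = 36)   # 8490 subjects
cal <- attr(cohort, "calibration")
sprintf("incidence %.3f | person-years (at risk) %.0f | r(pm25,o3) %.3f",
        cal$incidence, cal$person_years, cal$exposure_correlations["pm25", "o3"])
#> incidence 0.066 | person-years (at risk) 56574 | r(pm25,o3) 0.669

covs <- c(names(default_covariate_margins()), "temp")

# single-pollutant model: HR per quartile increment of PM2.5
cohort <- quantize(cohort, "pm25")
fit <- fit_cox(cohort, c("pm25_q", covs))
head(tidy(fit, exponentiate = TRUE), 3)
#>   term         estimate std.error statistic  p.value conf.low conf.high
#> 1 pm25_q           1.17    0.0383      4.08 4.41e- 5    1.08       1.26
#> 2 age_group65+     1.72    0.0847      6.38 1.77e-10    1.45       2.03
#> 3 sexfemale        1.12    0.0849      1.30 1.95e- 1    0.945      1.32

# mixture model: joint HR per simultaneous one-quantile increment
qg <- fit_qgcomp(cohort, mixture = c("pm25", "o3"), covariates = covs)
qg
#> <qgcomp_fit> psi = 0.1812 (SE 0.04439); joint HR 1.199 (1.099-1.308)
#>   exposure estimate std.error weight direction
#> 1 pm25       0.123     0.0486  0.679 positive
#> 2 o3         0.0581    0.0524  0.321 positive

# attributable fraction of the mixture, Monte-Carlo CI
paf_mc_ci(qg, n_draws = 10000, seed = 1)
#> <paf_estimate> mixture (single-increment): PAF = 4.73% (95% CI 2.39%-7.08%; 10000 draws)
```

Reading the output: the generator's default truth puts component per-quartile
log-HRs of 0.68·ln(1.18) on PM2.5 and 0.32·ln(1.18) on O3; in this cohort the
mixture fit recovers a joint HR of 1.199 with a 68%/32% weight split, and the
single-increment Levin PAF attributes 4.7% of events to the mixture. Single
cohorts scatter around the truth — the test suite averages such fits over
many seeds.

`spline_curve()`, `subgroup_fits()`, `heterogeneity_tests()`,
`build_report()` and `run_pipeline()` cover the rest of the chain;
`autoplot()` methods plot curves, weights and PAFs.

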