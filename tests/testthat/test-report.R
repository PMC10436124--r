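test_that("z_between matches its defining identities", {
  expect_equal(z_between(0.3, 0.1, 0.3, 0.2)$z, 0)
  expect_equal(z_between(0.3, 0.1, 0.3, 0.2)$p_raw, 1)
  # b1 - b2 = 1.96 * pooled SE gives p = 0.05 exactly
  se <- c(0.1, 0.15)
  delta <- qnorm(0.975) * sqrt(sum(se^2))
  expect_equal(z_between(delta, se[1], 0, se[2])$p_raw, 0.05, tolerance = 1e-12)
  expect_error(z_between(1, 0, 2, 1), "positive")
})

test_that("z_between is antisymmetric under swapping groups", {
  set.seed(91)
  for (rep in 1:10) {
    b <- rnorm(2); s <- runif(2, 0.05, 0.3)
    expect_equal(z_between(b[1], s[1], b[2], s[2])$z,
                 -z_between(b[2], s[2], b[1], s[1])$z)
  }
})

test_that("urban/rural PM2.5 heterogeneity back-calculated from printed CIs is significant", {
  rural <- c(hr = 1.54, lo = 1.30, hi = 1.83)
  urban <- c(hr = 0.89, lo = 0.76, hi = 1.05)
  zt <- z_between(log(rural["hr"]), se_from_hr_ci(rural["lo"], rural["hi"]),
                  log(urban["hr"]), se_from_hr_ci(urban["lo"], urban["hi"]))
  expect_equal(unname(zt$z), 4.57, tolerance = 0.01)
  expect_lt(zt$p_raw, 0.001)
})

test_that("bonferroni caps and dominates the raw p values", {
  expect_equal(bonferroni(0.01, 3), 0.03)
  expect_equal(bonferroni(0.5, 4), 1)
  set.seed(92)
  p <- runif(50)
  for (m in c(1, 3, 10)) expect_true(all(bonferroni(p, m) >= p))
  expect_error(bonferroni(1.2), "\\[0, 1\\]")
})

test_that("variance inflation factors follow the closed form", {
  # orthogonal columns
  X <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  expect_equal(unname(vif(X)), c(1, 1))

  # two columns with correlation 0.663: VIF = 1 / (1 - r^2)
  set.seed(93)
  n <- 20000
  z <- rnorm(n)
  x1 <- z
  x2 <- 0.663 * z + sqrt(1 - 0.663^2) * rnorm(n)
  v <- vif(cbind(x1, x2))
  expect_equal(unname(v[1]), 1 / (1 - cor(x1, x2)^2), tolerance = 1e-6)
  expect_equal(unname(v[1]), 1 / (1 - 0.663^2), tolerance = 0.05)

  # exact collinearity reported as infinite
  X2 <- cbind(x = rnorm(10) + 10)
  expect_true(is.infinite(vif(cbind(X2, 2 * X2))[1]))

  # the default multipollutant design is far from problematic collinearity
  cohort <- make_cohort(generator_config(n_subjects = 1200), seed = 94)
  cohort <- quantize(quantize(cohort, "pm25"), "o3")
  D <- airmix:::build_design(cohort, c("pm25_q", "o3_q", default_covs()))
  expect_true(all(vif(D) < 10))
})

test_that("temperature quartiles partition subjects into four groups", {
  cohort <- make_cohort(generator_config(n_subjects = 800), seed = 95)
  cohort <- temperature_quartiles(cohort)
  sub <- dplyr::distinct(cohort, subject_id, temp_q4)
  expect_equal(nrow(sub), 800)
  props <- as.numeric(table(sub$temp_q4)) / 800
  expect_true(all(abs(props - 0.25) < 0.05))
})

test_that("subgroup fits drop the subgroup variable and match manual refits", {
  cohort <- make_cohort(generator_config(n_subjects = 2500), seed = 96)
  covs <- default_covs()
  sub <- subgroup_fits(cohort, "urbanicity", covariates = covs)
  expect_setequal(unique(sub$level), c("rural", "urban"))
  expect_setequal(unique(sub$model), c("pm25", "o3", "joint"))

  # manual refit of one stratum: full-cohort cuts, adjustment set minus the
  # subgroup variable
  coh_q <- quantize(quantize(cohort, "pm25"), "o3")
  stratum <- coh_q[coh_q$urbanicity == "rural", ]
  manual <- fit_cox(stratum, c("pm25_q", setdiff(covs, "urbanicity")))
  got <- sub[sub$level == "rural" & sub$model == "pm25", ]
  expect_equal(got$log_hr, unname(manual$coefficients["pm25_q"]), tolerance = 1e-10)
  expect_false(any(grepl("urbanicity", names(manual$coefficients))))

  # without planted effect modification the stratum CIs overlap
  joint <- sub[sub$model == "joint", ]
  expect_lt(max(joint$conf.low), min(joint$conf.high))
})

test_that("strata without events are skipped with a warning", {
  cohort <- make_cohort(generator_config(n_subjects = 300), seed = 97)
  # confine all events to the rural stratum
  cohort$event[cohort$urbanicity == "urban"] <- 0L
  expect_warning(
    sub <- subgroup_fits(cohort, "urbanicity", covariates = c("sex", "temp")),
    "no events"
  )
  expect_setequal(unique(sub$level), "rural")
})

test_that("a planted obesity modifier raises the obese-stratum joint HR", {
  mult <- 2.5
  hrs <- t(vapply(1:3, function(s) {
    cohort <- make_cohort(generator_config(
      n_subjects = 4000,
      effect_modifiers = list(bmi_group = c(obese = mult))), seed = 100 + s)
    sub <- subgroup_fits(cohort, "bmi_group", covariates = default_covs())
    j <- sub[sub$model == "joint", ]
    c(obese = j$hr[j$level == "obese"], other = max(j$hr[j$level != "obese"]))
  }, c(obese = 0, other = 0)))
  expect_gt(mean(hrs[, "obese"]), mean(hrs[, "other"]))
})

test_that("heterogeneity tables use pairwise Bonferroni counts", {
  sub <- tibble::tibble(
    variable = "bmi_group", level = c("normal", "overweight", "obese"),
    n_subjects = 1, n_events = 1, model = "joint",
    log_hr = c(0.1, 0.05, 0.7), se = c(0.1, 0.12, 0.2),
    hr = exp(c(0.1, 0.05, 0.7)), conf.low = 1, conf.high = 1
  )
  het <- heterogeneity_tests(sub)
  expect_equal(nrow(het), 3)
  expect_true(all(het$m == 3))
  expect_equal(het$p_adjusted, pmin(1, 3 * het$p_raw))
})

test_that("build_report emits a stable schema that round-trips through CSV", {
  cohort <- make_cohort(generator_config(n_subjects = 900), seed = 98)
  cohort <- quantize(quantize(cohort, "pm25"), "o3")
  covs <- default_covs()
  fits <- list(pm25 = fit_cox(cohort, c("pm25_q", covs)),
               o3 = fit_cox(cohort, c("o3_q", covs)))
  qg <- fit_qgcomp(cohort, c("pm25", "o3"), covariates = covs)
  pafs <- list(joint = paf_mc_ci(qg, n_draws = 500, seed = 1))
  dir <- withr::local_tempdir()
  rep1 <- build_report(fits, qg, subgroups = NULL, pafs = pafs, output_dir = dir)

  expect_named(rep1$effects,
               c("variable", "level", "n_subjects", "n_events", "model",
                 "log_hr", "se", "hr", "conf.low", "conf.high"))
  expect_setequal(rep1$effects$model, c("pm25", "o3", "joint"))
  expect_equal(nrow(rep1$effects), 3)  # no subgroups: total rows only

  back <- readr::read_csv(file.path(dir, "effects.csv"), show_col_types = FALSE)
  expect_equal(back$hr, rep1$effects$hr, tolerance = 1e-12)
  expect_equal(back$log_hr, rep1$effects$log_hr, tolerance = 1e-12)
})
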