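#' Configuration for a full pipeline run
#'
#' @param generator A [generator_config()] to simulate a cohort, or a path to
#'   an existing person-period CSV (read with [read_cohort()]).
#' @param schema Schema used when `generator` is a CSV path; derived from the
#'   generator config otherwise.
#' @param mixture Mixture exposure columns.
#' @param covariates Adjustment columns; must be disjoint from `mixture`.
#'   Defaults to the schema covariates plus ambient temperature.
#' @param spline,single,joint Flags selecting which models run.
#' @param paf_model PAF prevalence model (see [paf_from_fit()]).
#' @param paf_draws Monte-Carlo draws for PAF intervals.
#' @param subgroups Character vector of subgroup variables (may include
#'   `"temp_q4"`, created via [temperature_quartiles()]).
#' @param seed Integer master seed; stage seeds are derived from it so each
#'   stage is independently reproducible.
#' @param output_dir Run directory (created if needed).
#' @return A `run_config` list.
#' @export
run_config <- function(generator = generator_config(), schema = NULL,
                       mixture = c("pm25", "o3"), covariates = NULL,
                       spline = TRUE, single = TRUE, joint = TRUE,
                       paf_model = "single-increment", paf_draws = 10000,
                       subgroups = character(), seed = 1,
                       output_dir = tempfile("airmix_run_")) {
  if (is.null(schema)) {
    schema <- if (inherits(generator, "generator_config")) config_schema(generator)
              else default_schema()
  }
  if (is.null(covariates)) {
    covariates <- c(schema_covariate_names(schema), "temp")
  }
  if (length(intersect(mixture, covariates)) > 0) {
    abort("`covariates` must be disjoint from `mixture`")
  }
  structure(list(generator = generator, schema = schema, mixture = mixture,
                 covariates = covariates, spline = spline, single = single,
                 joint = joint, paf_model = paf_model, paf_draws = paf_draws,
                 subgroups = subgroups, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the [run_config()] arguments; `generator` may be a
#' CSV path or a mapping of [generator_config()] arguments.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$generator) && is.list(y$generator)) {
    y$generator <- do.call(generator_config, y$generator)
  }
  do.call(run_config, y)
}

pipeline_log <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  writeLines(msg, con)
  message(msg)
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) a person-period cohort, quartile-code the mixture
#' exposures, fit the single-pollutant Cox models, natural-spline
#' exposure-response curves and the quantile g-computation mixture model,
#' compute individual and joint PAFs with Monte-Carlo intervals, run any
#' requested subgroup analyses with heterogeneity tests, and write every
#' result to the run directory (`cohort.csv`, `fit_<exposure>.json`,
#' `qgcomp.json`, `paf.json`, `spline_<exposure>.csv`, `effects.csv`,
#' `heterogeneity.csv`, `paf.csv`, `run.log`). Deterministic given the
#' config's seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the cohort, fits, PAFs, report tables and
#'   the run directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "run.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)
  pipeline_log(con, "airmix ", as.character(utils::packageVersion("airmix")),
               " | R ", R.version$major, ".", R.version$minor,
               " | seed ", config$seed)

  seed_sim <- config$seed
  seed_paf <- (config$seed + 104729L) %% .Machine$integer.max

  if (inherits(config$generator, "generator_config")) {
    pipeline_log(con, "simulating cohort (n = ", config$generator$n_subjects, ")")
    cohort <- make_cohort(config$generator, seed = seed_sim)
    cal <- attr(cohort, "calibration")
    pipeline_log(con, sprintf(
      "realized calibration: incidence %.4f, person-years %.0f, r(pm25,o3) %.3f, lambda0 %.3e",
      cal$incidence, cal$person_years,
      cal$exposure_correlations["pm25", "o3"], cal$lambda0))
    write_cohort(cohort, file.path(config$output_dir, "cohort.csv"))
  } else {
    pipeline_log(con, "reading cohort from ", config$generator)
    cohort <- read_cohort(config$generator, config$schema)
  }

  if ("temp_q4" %in% config$subgroups) cohort <- temperature_quartiles(cohort)
  for (e in config$mixture) cohort <- quantize(cohort, e)

  fit_json <- function(path, obj) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }

  single_fits <- list()
  pafs <- list()
  if (config$single) {
    for (i in seq_along(config$mixture)) {
      e <- config$mixture[i]
      pipeline_log(con, "single-pollutant fit: ", e)
      f <- fit_cox(cohort, c(paste0(e, "_q"), config$covariates))
      single_fits[[e]] <- f
      fit_json(file.path(config$output_dir, paste0("fit_", e, ".json")), list(
        coefficients = as.list(f$coefficients),
        vcov = f$vcov, loglik = f$loglik, n_events = f$n_events,
        converged = f$converged,
        hr_table = tidy(f, exponentiate = TRUE)
      ))
      pafs[[e]] <- paf_mc_ci(f, paste0(e, "_q"), config$paf_model,
                             n_draws = config$paf_draws,
                             seed = (seed_paf + i) %% .Machine$integer.max)
    }
  }

  qg <- NULL
  if (config$joint) {
    pipeline_log(con, "quantile g-computation: ", paste(config$mixture, collapse = " + "))
    qg <- fit_qgcomp(cohort, config$mixture, covariates = config$covariates)
    fit_json(file.path(config$output_dir, "qgcomp.json"), list(
      psi = qg$psi, psi_se = qg$psi_se, hr = qg$hr,
      conf.low = qg$conf.low, conf.high = qg$conf.high,
      components = qg$components
    ))
    pafs[["joint"]] <- paf_mc_ci(qg, prevalence_model = config$paf_model,
                                 n_draws = config$paf_draws, seed = seed_paf)
  }
  if (length(pafs) > 0) {
    fit_json(file.path(config$output_dir, "paf.json"),
             lapply(pafs, function(p) list(
               paf = 100 * p$point,
               conf.low = if (is.null(p$ci)) NULL else 100 * p$ci[1],
               conf.high = if (is.null(p$ci)) NULL else 100 * p$ci[2],
               n_draws = p$n_draws, model = p$prevalence_model)))
  }

  curves <- list()
  if (config$spline) {
    for (e in config$mixture) {
      pipeline_log(con, "spline curve: ", e)
      sc <- spline_curve(cohort, e, covariates = config$covariates)
      curves[[e]] <- sc
      readr::write_csv(sc$curve, file.path(config$output_dir, paste0("spline_", e, ".csv")),
                       progress = FALSE)
    }
  }

  sub_tbl <- NULL
  if (length(config$subgroups) > 0) {
    sub_list <- lapply(config$subgroups, function(v) {
      pipeline_log(con, "subgroup analysis: ", v)
      subgroup_fits(cohort, v, mixture = config$mixture,
                    covariates = config$covariates)
    })
    sub_tbl <- dplyr::bind_rows(sub_list)
  }

  report <- build_report(single_fits, qg, sub_tbl, pafs,
                         output_dir = config$output_dir)
  pipeline_log(con, "done: ", config$output_dir)
  invisible(list(cohort = cohort, single_fits = single_fits, qgcomp = qg,
                 splines = curves, pafs = pafs, subgroups = sub_tbl,
                 report = report, output_dir = config$output_dir))
}
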