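#' Two-sample z test for between-group heterogeneity
#'
#' Compares two log-scale estimates (e.g. stratum-specific log hazard ratios)
#' via `z = (b1 - b2) / sqrt(se1^2 + se2^2)` with a two-sided standard-normal
#' p value. Antisymmetric under swapping the groups.
#'
#' @param b1,b2 Log-scale estimates of the two groups.
#' @param se1,se2 Their standard errors (positive).
#' @return One-row tibble: `b1`, `se1`, `b2`, `se2`, `z`, `p_raw`.
#' @examples
#' z_between(log(1.54), se_from_hr_ci(1.30, 1.83),
#'           log(0.89), se_from_hr_ci(0.76, 1.05))
#' @export
z_between <- function(b1, se1, b2, se2) {
  if (any(c(se1, se2) <= 0)) abort("standard errors must be positive")
  z <- (b1 - b2) / sqrt(se1^2 + se2^2)
  tibble::tibble(b1 = b1, se1 = se1, b2 = b2, se2 = se2,
                 z = z, p_raw = 2 * pnorm(-abs(z)))
}

#' Bonferroni correction
#'
#' @param p Numeric vector of raw p values in \[0, 1\].
#' @param m Number of comparisons; defaults to `length(p)`.
#' @return `pmin(1, m * p)`.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1)) abort("p values must lie in [0, 1]")
  pmin(1, m * p)
}

#' Back-calculate a log-scale standard error from a printed hazard-ratio CI
#'
#' `SE = (log(upper) - log(lower)) / (2 * 1.96)`, the usual reconstruction
#' from a printed 95% Wald interval. Intended for consistency checks against
#' published tables.
#'
#' @param lower,upper Hazard-ratio confidence limits.
#' @return Standard error on the log scale.
#' @export
se_from_hr_ci <- function(lower, upper) {
  if (any(lower <= 0 | upper <= lower)) abort("need 0 < lower < upper")
  (log(upper) - log(lower)) / (2 * qnorm(0.975))
}

#' Variance inflation factors of a design matrix
#'
#' `VIF_k = 1 / (1 - R^2_k)` where `R^2_k` comes from the least-squares
#' regression of column `k` on the remaining columns (with intercept).
#' Exactly collinear columns are reported as `Inf`.
#'
#' @param design Numeric matrix with at least two columns.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(design) {
  design <- as.matrix(design)
  if (ncol(design) < 2) abort("need at least two columns")
  out <- vapply(seq_len(ncol(design)), function(k) {
    y <- design[, k]
    X <- cbind(1, design[, -k, drop = FALSE])
    fit <- lm.fit(X, y)
    ssr <- sum(fit$residuals^2)
    sst <- sum((y - mean(y))^2)
    if (sst == 0) return(Inf)
    r2 <- 1 - ssr / sst
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(design)
  out
}

#' Quartile groups of subject-mean temperature
#'
#' Adds a `temp_q4` factor (levels `Q1`-`Q4`) assigning each subject to a
#' quartile of its follow-up-mean temperature, for temperature subgrouping.
#'
#' @param data Person-period tibble with `subject_id` and `temp`.
#' @return `data` with the added `temp_q4` column.
#' @export
temperature_quartiles <- function(data) {
  means <- tapply(data$temp, data$subject_id, mean)
  cuts <- quantile(means, c(0.25, 0.5, 0.75), type = 7)
  grp <- factor(paste0("Q", quantile_code(means, cuts) + 1),
                levels = paste0("Q", 1:4))
  data$temp_q4 <- grp[match(as.character(data$subject_id), names(means))]
  data
}

#' Stratified single-pollutant and mixture fits
#'
#' Refits the single-pollutant Cox models and the quantile g-computation
#' mixture model within each level of a subgroup variable, adjusting for all
#' covariates except the subgroup variable itself. Quartile cut points are
#' taken from the full cohort so "per quartile increment" means the same
#' contrast in every stratum. Strata without events are skipped with a
#' warning.
#'
#' @param data Person-period tibble.
#' @param variable Subgroup column name (categorical).
#' @param mixture Mixture exposure columns (default `c("pm25", "o3")`).
#' @param covariates Full adjustment set; `variable` is removed from it.
#' @param ties Passed to the fitters.
#' @return Tibble with one row per stratum and model (`model` is the exposure
#'   name or `"joint"`): `variable`, `level`, `n_subjects`, `n_events`,
#'   `model`, `log_hr`, `se`, `hr`, `conf.low`, `conf.high`.
#' @export
subgroup_fits <- function(data, variable, mixture = c("pm25", "o3"),
                          covariates = character(), ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (is.null(data[[variable]])) abort(paste0("no column '", variable, "' in the data"))
  adj <- setdiff(covariates, variable)

  cuts <- list()
  for (e in mixture) {
    data <- quantize(data, e)
    cuts[[e]] <- attr(data, paste0("quantile_spec_", e))
  }

  levels_v <- if (is.factor(data[[variable]])) levels(droplevels(data[[variable]]))
              else sort(unique(as.character(data[[variable]])))
  rows <- list()
  for (lev in levels_v) {
    stratum <- data[as.character(data[[variable]]) == lev, , drop = FALSE]
    n_ev <- sum(stratum$event)
    n_subj <- length(unique(stratum$subject_id))
    if (n_ev == 0) {
      warn(paste0("stratum '", lev, "' of '", variable, "' has no events; skipped"))
      next
    }
    for (e in mixture) {
      f <- fit_cox(stratum, c(paste0(e, "_q"), adj), ties = ties)
      b <- unname(f$coefficients[paste0(e, "_q")])
      s <- sqrt(f$vcov[paste0(e, "_q"), paste0(e, "_q")])
      rows[[length(rows) + 1]] <- tibble::tibble(
        variable = variable, level = lev, n_subjects = n_subj,
        n_events = n_ev, model = e, log_hr = b, se = s,
        hr = exp(b), conf.low = exp(b - 1.96 * s), conf.high = exp(b + 1.96 * s)
      )
    }
    qg <- fit_qgcomp(stratum, mixture, covariates = adj, cuts = cuts, ties = ties)
    rows[[length(rows) + 1]] <- tibble::tibble(
      variable = variable, level = lev, n_subjects = n_subj,
      n_events = n_ev, model = "joint", log_hr = qg$psi, se = qg$psi_se,
      hr = qg$hr, conf.low = qg$conf.low, conf.high = qg$conf.high
    )
  }
  dplyr::bind_rows(rows)
}

#' Pairwise heterogeneity tests across subgroup strata
#'
#' Applies [z_between()] to every pair of levels within each model of a
#' [subgroup_fits()] table and Bonferroni-adjusts with `m` equal to the
#' number of pairwise level comparisons for the variable.
#'
#' @param subgroups Tibble from [subgroup_fits()].
#' @return Tibble: `variable`, `model`, `level1`, `level2`, `z`, `p_raw`,
#'   `p_adjusted`, `m`.
#' @export
heterogeneity_tests <- function(subgroups) {
  out <- list()
  for (v in unique(subgroups$variable)) {
    sv <- subgroups[subgroups$variable == v, ]
    levs <- unique(sv$level)
    m <- choose(length(levs), 2)
    if (m == 0) next
    for (mod in unique(sv$model)) {
      sm <- sv[sv$model == mod, ]
      if (nrow(sm) < 2) next
      pairs <- utils::combn(nrow(sm), 2)
      for (k in seq_len(ncol(pairs))) {
        i <- pairs[1, k]; j <- pairs[2, k]
        zt <- z_between(sm$log_hr[i], sm$se[i], sm$log_hr[j], sm$se[j])
        out[[length(out) + 1]] <- tibble::tibble(
          variable = v, model = mod,
          level1 = sm$level[i], level2 = sm$level[j],
          z = zt$z, p_raw = zt$p_raw,
          p_adjusted = bonferroni(zt$p_raw, m), m = m
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Assemble result tables
#'
#' Builds tidy effect, PAF and heterogeneity tables from total-cohort fits,
#' subgroup results and PAF estimates, optionally writing each as CSV.
#'
#' @param single_fits Named list of `cox_fit`s keyed by exposure (the
#'   per-quartile single-pollutant models); the quartile-score coefficient is
#'   assumed to be named `<exposure>_q`.
#' @param qg_fit A `qgcomp_fit` for the mixture (or `NULL`).
#' @param subgroups Tibble from [subgroup_fits()] (zero or more variables
#'   bound together), or `NULL`.
#' @param pafs Named list of `paf_estimate`s (or `NULL`).
#' @param output_dir Optional directory; writes `effects.csv`,
#'   `heterogeneity.csv` and `paf.csv` there.
#' @return List of tibbles: `effects`, `heterogeneity`, `paf`.
#' @export
build_report <- function(single_fits = list(), qg_fit = NULL, subgroups = NULL,
                         pafs = NULL, output_dir = NULL) {
  total <- list()
  for (e in names(single_fits)) {
    f <- single_fits[[e]]
    term <- paste0(e, "_q")
    b <- unname(f$coefficients[term])
    s <- sqrt(f$vcov[term, term])
    total[[length(total) + 1]] <- tibble::tibble(
      variable = "total", level = "total",
      n_subjects = f$n_subjects, n_events = f$n_events, model = e,
      log_hr = b, se = s, hr = exp(b),
      conf.low = exp(b - 1.96 * s), conf.high = exp(b + 1.96 * s)
    )
  }
  if (!is.null(qg_fit)) {
    total[[length(total) + 1]] <- tibble::tibble(
      variable = "total", level = "total",
      n_subjects = qg_fit$fit$n_subjects, n_events = qg_fit$fit$n_events,
      model = "joint", log_hr = qg_fit$psi, se = qg_fit$psi_se,
      hr = qg_fit$hr, conf.low = qg_fit$conf.low, conf.high = qg_fit$conf.high
    )
  }
  effects <- dplyr::bind_rows(c(total, list(subgroups)))
  het <- if (!is.null(subgroups) && nrow(subgroups) > 0) {
    heterogeneity_tests(subgroups)
  } else {
    tibble::tibble()
  }
  paf_tbl <- if (!is.null(pafs)) {
    dplyr::bind_rows(lapply(names(pafs), function(nm) {
      t <- tidy(pafs[[nm]]); t$exposure <- nm; t
    }))
  } else {
    tibble::tibble()
  }
  out <- list(effects = effects, heterogeneity = het, paf = paf_tbl)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(effects, file.path(output_dir, "effects.csv"), progress = FALSE)
    if (nrow(het) > 0) readr::write_csv(het, file.path(output_dir, "heterogeneity.csv"), progress = FALSE)
    if (nrow(paf_tbl) > 0) readr::write_csv(paf_tbl, file.path(output_dir, "paf.csv"), progress = FALSE)
  }
  out
}

#' Forest plot of subgroup hazard ratios
#'
#' @param subgroups Tibble from [subgroup_fits()].
#' @return A ggplot object, faceted by model.
#' @export
plot_subgroups <- function(subgroups) {
  ggplot2::ggplot(subgroups,
                  ggplot2::aes(x = .data$hr, y = interaction(.data$variable, .data$level))) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(~model) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (per quartile increment)", y = NULL) +
    ggplot2::theme_minimal()
}
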