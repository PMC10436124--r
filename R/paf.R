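#' Levin-type population-attributable fraction over exposure categories
#'
#' Multicategory Levin formula
#' `PAF = sum(p_i (RR_i - 1)) / (1 + sum(p_i (RR_i - 1)))`, with `p_i` the
#' population proportion in exposure category `i` and `RR_i` its relative
#' risk (hazard ratio) versus the reference category.
#'
#' @param p Numeric vector of non-reference category proportions
#'   (`sum(p) <= 1`).
#' @param rr Positive relative risks, one per category.
#' @return PAF point value (at most 1; 0 when all `rr` equal 1).
#' @examples
#' paf_levin(0.25, 2)      # 0.2
#' paf_levin(0.25, 1.18)   # ~0.0431
#' @export
paf_levin <- function(p, rr) {
  if (length(p) != length(rr)) abort("`p` and `rr` must have equal length")
  if (any(p < 0) || sum(p) > 1 + 1e-12) {
    abort("category proportions must be non-negative and sum to at most 1")
  }
  if (any(rr <= 0)) abort("relative risks must be positive")
  s <- sum(p * (rr - 1))
  s / (1 + s)
}

paf_categories <- function(log_hr, prevalence_model) {
  switch(prevalence_model,
    "single-increment" = list(p = 0.25, rr = exp(log_hr)),
    "multicategory" = list(p = rep(0.25, 3), rr = exp((1:3) * log_hr)),
    abort("`prevalence_model` must be \"single-increment\" or \"multicategory\"")
  )
}

# pull the relevant log-HR (or draws of it) out of a fit
paf_loghr <- function(fit, exposure) {
  if (inherits(fit, "qgcomp_fit")) {
    list(est = fit$psi,
         mean = fit$components$estimate,
         vcov = fit$vcov_components,
         combine = function(b) sum(b))
  } else if (inherits(fit, "cox_fit")) {
    if (is.null(exposure) || !exposure %in% names(fit$coefficients)) {
      abort("`exposure` must name a coefficient of the Cox fit")
    }
    list(est = unname(fit$coefficients[exposure]),
         mean = unname(fit$coefficients[exposure]),
         vcov = fit$vcov[exposure, exposure, drop = FALSE],
         combine = function(b) b)
  } else {
    abort("`fit` must be a cox_fit or qgcomp_fit")
  }
}

#' Population-attributable fraction from a fitted hazard ratio
#'
#' Applies the Levin formula to a fitted per-quartile (or mixture) log hazard
#' ratio. The default `"single-increment"` prevalence model treats the top
#' exposure quartile (proportion 0.25) as exposed at the per-quartile hazard
#' ratio; `"multicategory"` places 0.25 of the population in each
#' non-reference quartile `k` at `RR = exp(k * beta)`.
#'
#' @param fit A `cox_fit` or `qgcomp_fit` (converged).
#' @param exposure For a `cox_fit`, the coefficient name of the quartile
#'   score (e.g. `"pm25_q"`); ignored for a `qgcomp_fit` (the mixture index
#'   is used).
#' @param prevalence_model `"single-increment"` (default) or
#'   `"multicategory"`.
#' @return A `paf_estimate` with the point PAF (no Monte-Carlo draws; see
#'   [paf_mc_ci()]).
#' @export
paf_from_fit <- function(fit, exposure = NULL,
                         prevalence_model = c("single-increment", "multicategory")) {
  prevalence_model <- match.arg(prevalence_model)
  src <- paf_loghr(fit, exposure)
  cat_ <- paf_categories(src$est, prevalence_model)
  structure(list(
    point = paf_levin(cat_$p, cat_$rr),
    draws = NULL, ci = NULL, n_draws = 0L,
    prevalence_model = prevalence_model,
    inputs = list(log_hr = src$est, p = cat_$p, rr = cat_$rr),
    exposure = if (inherits(fit, "qgcomp_fit")) "mixture" else exposure
  ), class = "paf_estimate")
}

#' Monte-Carlo confidence interval for a PAF
#'
#' Draws coefficient vectors from the multivariate normal with the fitted
#' mean and variance-covariance matrix, maps each draw through the Levin
#' formula, and reports the percentile (2.5th, 97.5th) interval of the
#' resulting PAF draws. Reproducible under `seed`.
#'
#' @inheritParams paf_from_fit
#' @param n_draws Number of Monte-Carlo draws (default 10,000).
#' @param seed Optional integer seed.
#' @param repair_psd Repair a slightly indefinite covariance by clipping
#'   negative eigenvalues at zero (off by default; an indefinite covariance
#'   is an error otherwise).
#' @return A `paf_estimate` with `point`, `draws`, percentile `ci` and
#'   `n_draws`.
#' @examples
#' \donttest{
#' cohort <- make_cohort(generator_config(n_subjects = 500), seed = 2)
#' qg <- fit_qgcomp(cohort, c("pm25", "o3"), covariates = "age_group")
#' paf_mc_ci(qg, n_draws = 1000, seed = 1)
#' }
#' @export
paf_mc_ci <- function(fit, exposure = NULL,
                      prevalence_model = c("single-increment", "multicategory"),
                      n_draws = 10000, seed = NULL, repair_psd = FALSE) {
  prevalence_model <- match.arg(prevalence_model)
  src <- paf_loghr(fit, exposure)
  Sig <- as.matrix(src$vcov)
  ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) {
    if (!repair_psd) {
      abort("coefficient covariance is not positive semidefinite (set `repair_psd = TRUE` to clip)")
    }
    ed <- eigen(Sig, symmetric = TRUE)
    Sig <- ed$vectors %*% diag(pmax(ed$values, 0), nrow(Sig)) %*% t(ed$vectors)
  }
  if (!is.null(seed)) set.seed(seed)
  draws_beta <- MASS::mvrnorm(n_draws, mu = src$mean, Sigma = Sig)
  draws_beta <- matrix(draws_beta, nrow = n_draws)
  loghr_draws <- apply(draws_beta, 1, src$combine)
  paf_draws <- vapply(loghr_draws, function(b) {
    cat_ <- paf_categories(b, prevalence_model)
    paf_levin(cat_$p, cat_$rr)
  }, numeric(1))

  cat0 <- paf_categories(src$est, prevalence_model)
  structure(list(
    point = paf_levin(cat0$p, cat0$rr),
    draws = paf_draws,
    ci = unname(quantile(paf_draws, c(0.025, 0.975), type = 7)),
    n_draws = n_draws,
    prevalence_model = prevalence_model,
    inputs = list(log_hr = src$est, p = cat0$p, rr = cat0$rr),
    exposure = if (inherits(fit, "qgcomp_fit")) "mixture" else exposure
  ), class = "paf_estimate")
}

#' Combine independent PAFs by complement product
#'
#' `1 - prod(1 - PAF_i)`. Provided as a secondary utility for combining
#' attributable fractions of independent risk factors; the pipeline's
#' reported joint PAF is instead [paf_mc_ci()] applied to the quantile
#' g-computation mixture index, which accounts for the correlation between
#' the pollutants.
#'
#' @param pafs Numeric vector of PAF values, each < 1.
#' @return Combined PAF scalar.
#' @examples
#' paf_joint(c(0.0286, 0.0438))
#' @export
paf_joint <- function(pafs) {
  if (any(pafs >= 1)) abort("every PAF must be below 1")
  1 - prod(1 - pafs)
}

#' @export
print.paf_estimate <- function(x, ...) {
  cat("<paf_estimate> ", x$exposure, " (", x$prevalence_model, "): PAF = ",
      sprintf("%.2f%%", 100 * x$point), sep = "")
  if (!is.null(x$ci)) {
    cat(sprintf(" (95%% CI %.2f%%-%.2f%%; %d draws)",
                100 * x$ci[1], 100 * x$ci[2], x$n_draws))
  }
  cat("\n")
  invisible(x)
}

#' Tidy a PAF estimate
#'
#' @param x A `paf_estimate`.
#' @param ... Unused.
#' @return One-row tibble: `exposure`, `prevalence_model`, `paf`,
#'   `conf.low`, `conf.high` (on the percent scale), `n_draws`.
#' @export
tidy.paf_estimate <- function(x, ...) {
  tibble::tibble(
    exposure = x$exposure,
    prevalence_model = x$prevalence_model,
    paf = 100 * x$point,
    conf.low = if (is.null(x$ci)) NA_real_ else 100 * x$ci[1],
    conf.high = if (is.null(x$ci)) NA_real_ else 100 * x$ci[2],
    n_draws = x$n_draws
  )
}

#' Plot PAF estimates
#'
#' Forest-style display of one or more PAF estimates.
#'
#' @param pafs A list of `paf_estimate` objects (named or not) or a tibble
#'   from [tidy.paf_estimate()] rows.
#' @return A ggplot object.
#' @export
plot_paf <- function(pafs) {
  if (!is.data.frame(pafs)) {
    pafs <- dplyr::bind_rows(lapply(pafs, tidy))
  }
  ggplot2::ggplot(pafs, ggplot2::aes(x = .data$paf, y = .data$exposure)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.2, na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Population-attributable fraction (%)", y = NULL) +
    ggplot2::theme_minimal()
}
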