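#' Quantile g-computation with a Cox underlying model
#'
#' Estimates the joint effect of an exposure mixture: each exposure is
#' quartile-coded 0-3 and entered as a numeric score in a counting-process
#' Cox model alongside the covariates; the mixture index coefficient is
#' `psi = sum` of the exposure coefficients, interpreted as the log hazard
#' ratio for a simultaneous one-quartile increment of every exposure, with
#' `var(psi) = 1' Sigma 1` from the coefficient covariance (Wald interval).
#'
#' Weights follow the usual sign convention: when all component coefficients
#' share a sign, `w_j = beta_j / psi` and the weights sum to 1; when signs
#' differ, positive-direction weights sum to 1 over the positive
#' coefficients and negative-direction weights sum to 1 over the negative
#' ones (2 in total).
#'
#' @param data Person-period tibble.
#' @param mixture Character vector (>= 2 unless `allow_single`) of exposure
#'   columns forming the mixture.
#' @param covariates Character vector of adjustment columns (kept out of the
#'   mixture; e.g. ambient temperature is an adjustment covariate, not a
#'   mixture member).
#' @param cuts Optional named list of [quantile_spec()]s keyed by exposure;
#'   by default each exposure is quartile-coded with its own empirical cut
#'   points from `data`.
#' @param ties,tol,max_iter Passed to [fit_cox()].
#' @param allow_single Permit a single-exposure (degenerate) mixture.
#' @return A `qgcomp_fit`: `psi`, `psi_se`, joint hazard ratio with Wald CI,
#'   per-component tibble (`exposure`, `estimate`, `weight`, `direction`),
#'   component covariance, and the underlying `cox_fit`.
#' @examples
#' \donttest{
#' cohort <- make_cohort(generator_config(n_subjects = 400), seed = 7)
#' fit_qgcomp(cohort, mixture = c("pm25", "o3"),
#'            covariates = c("age_group", "sex", "temp"))
#' }
#' @export
fit_qgcomp <- function(data, mixture, covariates = character(), cuts = NULL,
                       ties = c("efron", "breslow"), tol = 1e-8,
                       max_iter = 25, allow_single = FALSE) {
  ties <- match.arg(ties)
  if (length(mixture) < 2 && !allow_single) {
    abort("a mixture needs at least 2 exposures (set `allow_single = TRUE` to override)")
  }
  used_cuts <- list()
  for (e in mixture) {
    spec <- if (!is.null(cuts[[e]])) cuts[[e]] else "empirical"
    data <- quantize(data, e, spec)
    used_cuts[[e]] <- attr(data, paste0("quantile_spec_", e))
  }
  score_cols <- paste0(mixture, "_q")
  fit <- fit_cox(data, c(score_cols, covariates), ties = ties, tol = tol,
                 max_iter = max_iter)

  beta <- fit$coefficients[score_cols]
  Sig <- fit$vcov[score_cols, score_cols, drop = FALSE]
  psi <- sum(beta)
  psi_var <- sum(Sig)
  psi_se <- sqrt(max(psi_var, 0))

  pos <- beta > 0
  if (all(pos) || all(!pos)) {
    weights <- beta / psi
    direction <- ifelse(pos, "positive", "negative")
  } else {
    weights <- numeric(length(beta))
    weights[pos] <- beta[pos] / sum(beta[pos])
    weights[!pos] <- beta[!pos] / sum(beta[!pos])
    direction <- ifelse(pos, "positive", "negative")
  }

  components <- tibble::tibble(
    exposure = mixture,
    estimate = unname(beta),
    std.error = sqrt(diag(Sig)),
    weight = unname(weights),
    direction = direction
  )
  structure(list(
    psi = psi, psi_se = psi_se,
    hr = exp(psi),
    conf.low = exp(psi - 1.96 * psi_se),
    conf.high = exp(psi + 1.96 * psi_se),
    components = components,
    vcov_components = Sig,
    cuts = used_cuts,
    mixture = mixture,
    fit = fit
  ), class = "qgcomp_fit")
}

#' @export
print.qgcomp_fit <- function(x, ...) {
  cat("<qgcomp_fit> psi = ", signif(x$psi, 4), " (SE ", signif(x$psi_se, 4),
      "); joint HR ", signif(x$hr, 4), " (", signif(x$conf.low, 4), "-",
      signif(x$conf.high, 4), ")\n", sep = "")
  print(x$components)
  invisible(x)
}

#' Tidy a quantile g-computation fit
#'
#' @param x A `qgcomp_fit`.
#' @param ... Unused.
#' @return The per-component tibble (`exposure`, `estimate`, `std.error`,
#'   `weight`, `direction`).
#' @export
tidy.qgcomp_fit <- function(x, ...) x$components

#' Model-level summary of a quantile g-computation fit
#'
#' @param x A `qgcomp_fit`.
#' @param ... Unused.
#' @return One-row tibble with `psi`, `psi_se`, the joint hazard ratio and
#'   its Wald CI, and the underlying fit's counts.
#' @export
glance.qgcomp_fit <- function(x, ...) {
  tibble::tibble(
    psi = x$psi, psi_se = x$psi_se, hr = x$hr,
    conf.low = x$conf.low, conf.high = x$conf.high,
    n_records = x$fit$n_records, n_events = x$fit$n_events,
    converged = x$fit$converged
  )
}

#' Plot mixture component weights
#'
#' @param object A `qgcomp_fit`.
#' @param ... Unused.
#' @return A ggplot bar chart of component weights by direction.
#' @export
autoplot.qgcomp_fit <- function(object, ...) {
  ggplot2::ggplot(object$components,
                  ggplot2::aes(x = .data$exposure, y = .data$weight,
                               fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Mixture weight") +
    ggplot2::theme_minimal()
}
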