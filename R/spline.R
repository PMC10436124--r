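#' Natural-spline exposure-response curve from a Cox model
#'
#' Replaces the linear exposure term with a natural cubic spline basis with 3
#' degrees of freedom (interior knots at the 33.3rd/66.7th percentiles of the
#' exposure over all person-period records, boundary knots at the 1st/99th
#' percentiles), refits the Cox model with the same covariate adjustment, and
#' reports the fitted log hazard ratio along an exposure grid relative to a
#' reference exposure, with delta-method pointwise confidence bands. The
#' curve is exactly 0 (with zero-width CI) at the reference.
#'
#' @param data Person-period tibble.
#' @param exposure Continuous exposure column name.
#' @param covariates Character vector of adjustment columns.
#' @param df Spline degrees of freedom (fixed at 3).
#' @param reference Reference exposure value; defaults to the median over
#'   records.
#' @param grid_n Number of grid points across the boundary-knot range.
#' @param ties,tol,max_iter Passed to [fit_cox()].
#' @param conf.level Confidence level for the pointwise bands.
#' @return A `spline_curve`: list with `curve` (tibble of `exposure`,
#'   `log_hr`, `se`, `hr`, `conf.low`, `conf.high`), `reference`, `knots`,
#'   `boundary`, and the underlying `fit`.
#' @seealso [autoplot.spline_curve()]
#' @export
spline_curve <- function(data, exposure, covariates = character(),
                         df = 3, reference = NULL, grid_n = 100,
                         ties = c("efron", "breslow"), tol = 1e-8,
                         max_iter = 25, conf.level = 0.95) {
  ties <- match.arg(ties)
  if (df != 3) abort("only df = 3 is supported")
  x <- data[[exposure]]
  if (is.null(x)) abort(paste0("no column '", exposure, "' in the data"))

  boundary <- unname(quantile(x, c(0.01, 0.99), type = 7))
  knots <- unname(quantile(x, c(1, 2) / 3, type = 7))
  if (any(diff(c(boundary[1], knots, boundary[2])) <= 0)) {
    abort("degenerate spline knots: exposure has too little spread")
  }
  basis <- splines::ns(x, knots = knots, Boundary.knots = boundary)
  if (ncol(basis) != df) abort("spline basis is rank-deficient")

  bnames <- paste0(".ns", seq_len(df))
  dat <- data
  for (j in seq_len(df)) dat[[bnames[j]]] <- basis[, j]
  fit <- fit_cox(dat, c(bnames, covariates), ties = ties, tol = tol,
                 max_iter = max_iter)

  if (is.null(reference)) reference <- median(x)
  grid <- sort(unique(c(seq(boundary[1], boundary[2], length.out = grid_n),
                        reference)))
  Bg <- stats::predict(basis, grid)
  Br <- stats::predict(basis, reference)
  D <- sweep(Bg, 2, drop(Br))
  beta_s <- fit$coefficients[seq_len(df)]
  Sig_s <- fit$vcov[seq_len(df), seq_len(df), drop = FALSE]
  log_hr <- drop(D %*% beta_s)
  se <- sqrt(pmax(rowSums((D %*% Sig_s) * D), 0))
  z <- qnorm(1 - (1 - conf.level) / 2)

  curve <- tibble::tibble(
    exposure = grid, log_hr = log_hr, se = se,
    hr = exp(log_hr),
    conf.low = exp(log_hr - z * se),
    conf.high = exp(log_hr + z * se)
  )
  structure(list(curve = curve, exposure = exposure, reference = reference,
                 knots = knots, boundary = boundary, df = df, fit = fit),
            class = "spline_curve")
}

#' @export
print.spline_curve <- function(x, ...) {
  cat("<spline_curve> ", x$exposure, ", df = ", x$df,
      ", reference = ", signif(x$reference, 5),
      ", knots at ", paste(signif(x$knots, 5), collapse = " / "), "\n", sep = "")
  print(x$curve, n = 5)
  invisible(x)
}

#' Plot an exposure-response curve
#'
#' Hazard ratio (relative to the reference exposure) with its pointwise
#' confidence ribbon.
#'
#' @param object A [spline_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spline_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$exposure, y = .data$hr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$reference, linetype = "dotted") +
    ggplot2::labs(x = object$exposure, y = "Hazard ratio") +
    ggplot2::theme_minimal()
}

#' @export
autoplot <- function(object, ...) UseMethod("autoplot")
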