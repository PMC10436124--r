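#' Build a Cox design matrix from cohort columns
#'
#' Numeric columns enter as-is; categorical columns are treatment-coded
#' against their first (reference) level. Factor levels unobserved in `data`
#' are dropped, and single-level factors contribute no column (a constant
#' cancels in the partial likelihood).
#'
#' @param data Person-period tibble.
#' @param terms Character vector of column names (exposure scores and
#'   covariates).
#' @return Numeric matrix with one row per record.
#' @keywords internal
build_design <- function(data, terms) {
  cols <- list()
  for (v in terms) {
    x <- data[[v]]
    if (is.null(x)) abort(paste0("no column '", v, "' in the data"))
    if (is.numeric(x)) {
      cols[[v]] <- as.numeric(x)
    } else {
      f <- droplevels(as.factor(x))
      if (anyNA(f)) abort(paste0("missing values in covariate '", v, "'"))
      for (l in levels(f)[-1]) cols[[paste0(v, l)]] <- as.numeric(f == l)
    }
  }
  if (length(cols) == 0) abort("design matrix has no columns")
  do.call(cbind, cols)
}

cox_engine_inputs <- function(data, terms) {
  for (v in c("start", "stop", "event")) {
    if (is.null(data[[v]])) abort(paste0("cohort is missing column '", v, "'"))
  }
  X <- build_design(data, terms)
  if (anyNA(X)) abort("missing values in the design matrix")
  list(X = X, start = as.numeric(data$start), stop = as.numeric(data$stop),
       event = as.integer(data$event))
}

#' Cox partial log-likelihood with analytic derivatives
#'
#' Evaluates the counting-process Cox partial log-likelihood, its gradient
#' and Hessian at a given coefficient vector, with Efron or Breslow handling
#' of tied event times. The risk set at an event time `t` contains the
#' records with `start < t <= stop`.
#'
#' @param data Person-period tibble with `start`, `stop`, `event` and the
#'   model columns.
#' @param beta Numeric coefficient vector, one per design-matrix column.
#' @param terms Character vector of model columns (see [build_design()]).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return List: `loglik` (scalar), `gradient`, `hessian` (the Hessian of the
#'   log-likelihood, negative semidefinite).
#' @examples
#' d <- tibble::tibble(start = 0, stop = 1:4, event = c(0, 0, 0, 1),
#'                     x = c(0.1, -0.2, 0.3, 0))
#' partial_loglik(d, beta = 0, terms = "x")$loglik  # -log(4)
#' @export
partial_loglik <- function(data, beta, terms, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  inp <- cox_engine_inputs(data, terms)
  if (sum(inp$event) == 0) abort("no events in the data")
  if (length(beta) != ncol(inp$X)) {
    abort(paste0("`beta` has length ", length(beta), " but the design has ",
                 ncol(inp$X), " column(s)"))
  }
  res <- .cox_loglik_cpp(inp$X, inp$start, inp$stop, inp$event,
                         as.numeric(beta), ties == "efron")
  list(loglik = res$loglik, gradient = drop(res$gradient),
       hessian = -res$information)
}

# name the design column dominating the information matrix's null space
name_singular_column <- function(info, cols) {
  ev <- eigen(info, symmetric = TRUE)
  v <- ev$vectors[, which.min(abs(ev$values))]
  cols[which.max(abs(v))]
}

#' Fit a Cox proportional-hazards model on counting-process data
#'
#' Newton-Raphson maximization of the partial likelihood with step-halving,
#' analytic gradient/Hessian from the compiled engine, and
#' covariance taken as the inverse observed information at the optimum.
#' Convergence requires the score max-norm below `tol` or a relative
#' log-likelihood change below 1e-10.
#'
#' @param data Person-period tibble (`start`, `stop`, `event` plus model
#'   columns).
#' @param terms Character vector of model columns: exposure scores (e.g. a
#'   quartile-coded `pm25_q` entered as numeric 0-3) and covariates.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param tol Convergence tolerance on the score max-norm.
#' @param max_iter Maximum Newton iterations.
#' @return A `cox_fit`: coefficients, `vcov`, log partial likelihood (fitted
#'   and null), event/record counts, convergence and monotone-likelihood
#'   flags.
#' @seealso [tidy.cox_fit()], [glance.cox_fit()], [spline_curve()]
#' @export
fit_cox <- function(data, terms, ties = c("efron", "breslow"),
                    tol = 1e-8, max_iter = 25) {
  ties <- match.arg(ties)
  inp <- cox_engine_inputs(data, terms)
  if (sum(inp$event) == 0) abort("no events in the data")
  X <- inp$X
  p <- ncol(X)

  eval_at <- function(beta) {
    .cox_loglik_cpp(X, inp$start, inp$stop, inp$event, beta, ties == "efron")
  }

  beta <- numeric(p)
  cur <- eval_at(beta)
  loglik_null <- cur$loglik
  monotone <- FALSE
  converged <- FALSE
  iter <- 0

  while (iter < max_iter) {
    iter <- iter + 1
    g <- drop(cur$gradient)
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(cur$information, g), error = function(e) NULL)
    if (is.null(step)) {
      abort(paste0("singular information matrix; offending column: ",
                   name_singular_column(cur$information, colnames(X))))
    }
    new_beta <- beta + drop(step)
    new <- eval_at(new_beta)
    halvings <- 0
    while ((!is.finite(new$loglik) || new$loglik < cur$loglik - 1e-9) && halvings < 20) {
      halvings <- halvings + 1
      new_beta <- beta + drop(step) / 2^halvings
      new <- eval_at(new_beta)
    }
    rel_change <- abs(new$loglik - cur$loglik) / (abs(cur$loglik) + 1e-12)
    beta <- new_beta
    cur <- new
    if (max(abs(beta)) > 15) monotone <- TRUE
    if (rel_change < 1e-10) {
      converged <- max(abs(drop(cur$gradient))) < sqrt(tol)
      break
    }
  }
  if (!converged && max(abs(drop(cur$gradient))) < tol) converged <- TRUE
  if (monotone) {
    warn("possible monotone likelihood: coefficients are diverging")
  }

  vcov <- tryCatch(solve(cur$information), error = function(e) {
    abort(paste0("singular information matrix; offending column: ",
                 name_singular_column(cur$information, colnames(X))))
  })
  vcov <- (vcov + t(vcov)) / 2
  names(beta) <- colnames(X)
  dimnames(vcov) <- list(colnames(X), colnames(X))

  structure(list(
    coefficients = beta, vcov = vcov,
    loglik = cur$loglik, loglik_null = loglik_null,
    n_events = sum(inp$event), n_records = nrow(X),
    n_subjects = if ("subject_id" %in% names(data)) length(unique(data[["subject_id"]])) else NA_integer_,
    converged = converged, monotone = monotone,
    ties = ties, iter = iter, terms = terms
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit> ", x$n_events, " events / ", x$n_records, " records; ties = ",
      x$ties, if (!x$converged) "; NOT converged" else "", "\n", sep = "")
  print(tidy(x, exponentiate = TRUE), ...)
  invisible(x)
}

#' @export
vcov.cox_fit <- function(object, ...) object$vcov

#' @export
coef.cox_fit <- function(object, ...) object$coefficients

#' @export
logLik.cox_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients), class = "logLik")
}

#' Tidy a Cox fit
#'
#' One row per coefficient, broom-style.
#'
#' @param x A `cox_fit`.
#' @param exponentiate If `TRUE`, report hazard ratios and CI on the hazard
#'   ratio scale.
#' @param conf.level Confidence level for Wald intervals.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.cox_fit <- function(x, exponentiate = FALSE, conf.level = 0.95, ...) {
  est <- x$coefficients
  se <- sqrt(diag(x$vcov))
  z <- qnorm(1 - (1 - conf.level) / 2)
  out <- tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * pnorm(-abs(unname(est / se))),
    conf.low = unname(est - z * se),
    conf.high = unname(est + z * se)
  )
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' Model-level summary of a Cox fit
#'
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @return One-row tibble: record/event counts, log partial likelihoods,
#'   iteration count, convergence flags, ties method.
#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(
    n_records = x$n_records, n_events = x$n_events, n_subjects = x$n_subjects,
    loglik = x$loglik, loglik_null = x$loglik_null,
    iter = x$iter, converged = x$converged, monotone = x$monotone,
    ties = x$ties
  )
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
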