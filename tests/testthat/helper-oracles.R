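# Independent oracles and small fixture builders used across the suite.

# Brute-force Cox partial log-likelihood by direct risk-set enumeration.
# Risk set at event time t: records with start < t <= stop. Efron or Breslow
# tie corrections. Deliberately O(events x records); independent of the
# compiled sweep it checks.
brute_force_coxll <- function(beta, X, start, stop, event, ties = "efron") {
  X <- as.matrix(X)
  lp <- drop(X %*% beta)
  w <- exp(lp)
  ll <- 0
  for (t in sort(unique(stop[event == 1]))) {
    risk <- which(start < t & t <= stop)
    deaths <- which(event == 1 & stop == t)
    d <- length(deaths)
    ll <- ll + sum(lp[deaths])
    for (k in seq_len(d) - 1) {
      f <- if (ties == "efron") k / d else 0
      ll <- ll - log(sum(w[risk]) - f * sum(w[deaths]))
    }
  }
  ll
}

# numerical gradient of a scalar function (central differences)
num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# a hand-written 3-subject counting-process fixture with one covariate
toy_cohort3 <- function() {
  tibble::tibble(
    subject_id = c(1L, 1L, 2L, 2L, 3L),
    start = c(0, 1, 0, 1, 0),
    stop = c(1, 2.5, 1, 1.8, 1.2),
    event = c(0L, 1L, 0L, 0L, 1L),
    x = c(0.2, 0.5, -0.3, 0.1, 0.8)
  )
}

# random small counting-process cohorts for oracle comparisons
random_cohort <- function(n_subjects = 40, p = 2, tie_prone = FALSE) {
  rows <- lapply(seq_len(n_subjects), function(i) {
    k <- sample(1:3, 1)
    bounds <- cumsum(if (tie_prone) sample(1:3, k, replace = TRUE) / 2
                     else round(runif(k, 0.3, 2), 2))
    tibble::tibble(
      subject_id = i,
      start = c(0, bounds[-k]),
      stop = bounds,
      event = c(rep(0L, k - 1), rbinom(1, 1, 0.5))
    )
  })
  d <- dplyr::bind_rows(rows)
  for (j in seq_len(p)) d[[paste0("x", j)]] <- round(rnorm(nrow(d)), 2)
  d[d$stop > d$start, ]
}

# truncated-power-basis natural cubic spline (independent of splines::ns):
# cubic spline basis linear beyond the boundary knots.
natural_spline_tp <- function(x, knots, boundary) {
  all_k <- c(boundary[1], knots, boundary[2])
  K <- length(all_k)
  d <- function(z, j) {
    (pmax(x - all_k[j], 0)^3 - pmax(x - all_k[K], 0)^3) / (all_k[K] - all_k[j])
  }
  cols <- lapply(seq_len(K - 2), function(j) d(x, j) - d(x, K - 1))
  cbind(x, do.call(cbind, cols))
}

# small generator config for fast simulation-based tests
small_config <- function(...) {
  generator_config(n_subjects = 600, ...)
}

default_covs <- function() c(names(default_covariate_margins()), "temp")
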