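// Counting-process Cox partial likelihood with analytic derivatives.
//
// Records are intervals (start, stop] with a 0/1 event flag at `stop`.
// The risk set at an event time t is {i : start_i < t <= stop_i}.
// A single ascending sweep over the distinct event times maintains the
// risk-set sums S0 = sum w, S1 = sum w x, S2 = sum w x x' incrementally:
// records are added once their entry time lies strictly before t and
// subtracted once their exit time lies strictly before t, so the total
// cost is O(n log n + n p^2) per evaluation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".cox_loglik_cpp")]]
Rcpp::List cox_loglik_cpp(const arma::mat& X,
                          const arma::vec& start,
                          const arma::vec& stop,
                          const arma::ivec& event,
                          const arma::vec& beta,
                          const bool efron) {
  const uword n = X.n_rows;
  const uword p = X.n_cols;

  vec lp = X * beta;
  // centring cancels exactly in every term of the partial likelihood
  const double lp_c = mean(lp);
  vec w = exp(lp - lp_c);
  for (uword i = 0; i < n; ++i) {
    if (!std::isfinite(w(i))) {
      Rcpp::stop("non-finite risk weight at record %d", (int)(i + 1));
    }
  }

  // distinct event times, ascending
  std::vector<uword> death_idx;
  death_idx.reserve(n);
  for (uword i = 0; i < n; ++i) {
    if (event(i) == 1) death_idx.push_back(i);
  }
  if (death_idx.empty()) Rcpp::stop("no events in the data");
  std::sort(death_idx.begin(), death_idx.end(),
            [&](uword a, uword b) { return stop(a) < stop(b); });

  uvec by_start = sort_index(start);   // additions
  uvec by_stop  = sort_index(stop);    // removals

  double ll = 0.0;
  vec grad(p, fill::zeros);
  mat info(p, p, fill::zeros);

  double s0 = 0.0;
  vec s1(p, fill::zeros);
  mat s2(p, p, fill::zeros);

  uword ia = 0, ir = 0;        // pointers into by_start / by_stop
  size_t id = 0;               // pointer into death_idx

  while (id < death_idx.size()) {
    const double t = stop(death_idx[id]);

    while (ia < n && start(by_start(ia)) < t) {
      const uword k = by_start(ia);
      const rowvec xk = X.row(k);
      s0 += w(k);
      s1 += w(k) * xk.t();
      s2 += w(k) * (xk.t() * xk);
      ++ia;
    }
    while (ir < n && stop(by_stop(ir)) < t) {
      const uword k = by_stop(ir);
      const rowvec xk = X.row(k);
      s0 -= w(k);
      s1 -= w(k) * xk.t();
      s2 -= w(k) * (xk.t() * xk);
      ++ir;
    }

    // gather the deaths tied at t
    double d0 = 0.0, lp_sum = 0.0;
    vec d1(p, fill::zeros), x_sum(p, fill::zeros);
    mat d2(p, p, fill::zeros);
    uword d = 0;
    while (id < death_idx.size() && stop(death_idx[id]) == t) {
      const uword k = death_idx[id];
      const rowvec xk = X.row(k);
      d0 += w(k);
      d1 += w(k) * xk.t();
      d2 += w(k) * (xk.t() * xk);
      lp_sum += lp(k) - lp_c;
      x_sum += xk.t();
      ++d;
      ++id;
    }

    ll += lp_sum;
    for (uword j = 0; j < d; ++j) {
      const double f = efron ? (double)j / (double)d : 0.0;
      const double denom = s0 - f * d0;
      if (denom <= 0.0) Rcpp::stop("empty risk set at an event time");
      const vec u = (s1 - f * d1) / denom;
      ll -= std::log(denom);
      grad -= u;
      info += (s2 - f * d2) / denom - u * u.t();
    }
    grad += x_sum;
  }

  return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                            Rcpp::Named("gradient") = grad,
                            Rcpp::Named("information") = info);
}
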