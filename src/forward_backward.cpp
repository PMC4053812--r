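#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward pass for a 2-state HMM over one uninterrupted
// block of CpGs. Emissions arrive as log densities (n x 2); the chain is
// restarted with `init` at the block start. Returns per-site posteriors,
// expected transition counts and the block log-likelihood.
// [[Rcpp::export(name = ".fb_block")]]
List fb_block(NumericMatrix logem, NumericMatrix trans, NumericVector init) {
  const int n = logem.nrow();
  NumericMatrix gamma(n, 2);
  NumericMatrix xi(2, 2);
  double loglik = 0.0;

  // emissions rescaled per site to avoid underflow
  NumericMatrix em(n, 2);
  NumericVector shift(n);
  for (int t = 0; t < n; ++t) {
    double m = std::max(logem(t, 0), logem(t, 1));
    shift[t] = m;
    em(t, 0) = std::exp(logem(t, 0) - m);
    em(t, 1) = std::exp(logem(t, 1) - m);
  }

  NumericMatrix alpha(n, 2);
  NumericVector c(n);
  alpha(0, 0) = init[0] * em(0, 0);
  alpha(0, 1) = init[1] * em(0, 1);
  c[0] = alpha(0, 0) + alpha(0, 1);
  alpha(0, 0) /= c[0];
  alpha(0, 1) /= c[0];
  for (int t = 1; t < n; ++t) {
    for (int j = 0; j < 2; ++j) {
      alpha(t, j) = (alpha(t - 1, 0) * trans(0, j) +
                     alpha(t - 1, 1) * trans(1, j)) * em(t, j);
    }
    c[t] = alpha(t, 0) + alpha(t, 1);
    alpha(t, 0) /= c[t];
    alpha(t, 1) /= c[t];
  }
  for (int t = 0; t < n; ++t) loglik += std::log(c[t]) + shift[t];

  NumericMatrix beta(n, 2);
  beta(n - 1, 0) = 1.0;
  beta(n - 1, 1) = 1.0;
  for (int t = n - 2; t >= 0; --t) {
    for (int i = 0; i < 2; ++i) {
      beta(t, i) = (trans(i, 0) * em(t + 1, 0) * beta(t + 1, 0) +
                    trans(i, 1) * em(t + 1, 1) * beta(t + 1, 1)) / c[t + 1];
    }
  }

  for (int t = 0; t < n; ++t) {
    double g0 = alpha(t, 0) * beta(t, 0);
    double g1 = alpha(t, 1) * beta(t, 1);
    double s = g0 + g1;
    gamma(t, 0) = g0 / s;
    gamma(t, 1) = g1 / s;
  }

  for (int t = 0; t < n - 1; ++t) {
    double denom = 0.0;
    double raw[2][2];
    for (int i = 0; i < 2; ++i) {
      for (int j = 0; j < 2; ++j) {
        raw[i][j] = alpha(t, i) * trans(i, j) * em(t + 1, j) *
                    beta(t + 1, j) / c[t + 1];
        denom += raw[i][j];
      }
    }
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j) xi(i, j) += raw[i][j] / denom;
  }

  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["loglik"] = loglik);
}
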