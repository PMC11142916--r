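#include <Rcpp.h>
using namespace Rcpp;

// Gaussian emission log-density
static inline double ldnorm(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return -0.5 * z * z - std::log(sd) - 0.9189385332046727;
}

// Scaled forward-backward for a K-state Gaussian-emission HMM.
// Returns log-likelihood, posterior state probabilities gamma (n x K),
// and summed transition posteriors xi (K x K) for the M-step.
// [[Rcpp::export]]
List hmm_forward_backward(NumericVector x, NumericVector mu, NumericVector sd,
                          NumericMatrix trans, NumericVector init) {
  const int n = x.size(), K = mu.size();
  NumericMatrix b(n, K);        // emission densities, scaled per row
  NumericMatrix alpha(n, K), beta(n, K), gamma(n, K);
  NumericMatrix xi(K, K);
  NumericVector c(n);           // forward scaling factors
  double loglik = 0.0;

  for (int t = 0; t < n; ++t) {
    double mx = R_NegInf;
    for (int k = 0; k < K; ++k) {
      b(t, k) = ldnorm(x[t], mu[k], sd[k]);
      if (b(t, k) > mx) mx = b(t, k);
    }
    for (int k = 0; k < K; ++k) b(t, k) = std::exp(b(t, k) - mx);
    loglik += mx;               // reinstated via the per-row shift
  }

  // forward
  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = init[k] * b(0, k); s += alpha(0, k); }
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < n; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * trans(j, k);
      alpha(t, k) = a * b(t, k);
      s += alpha(t, k);
    }
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }
  for (int t = 0; t < n; ++t) loglik += std::log(c[t]);

  // backward
  for (int k = 0; k < K; ++k) beta(n - 1, k) = 1.0;
  for (int t = n - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int k = 0; k < K; ++k) a += trans(j, k) * b(t + 1, k) * beta(t + 1, k);
      beta(t, j) = a / c[t + 1];
    }
  }

  for (int t = 0; t < n; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }
  for (int t = 0; t < n - 1; ++t) {
    double z = 0.0;
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        z += alpha(t, j) * trans(j, k) * b(t + 1, k) * beta(t + 1, k);
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi(j, k) += alpha(t, j) * trans(j, k) * b(t + 1, k) * beta(t + 1, k) / z;
  }

  return List::create(_["loglik"] = loglik, _["gamma"] = gamma, _["xi"] = xi);
}

// Viterbi path (1-based state indices).
// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericVector x, NumericVector mu, NumericVector sd,
                          NumericMatrix trans, NumericVector init) {
  const int n = x.size(), K = mu.size();
  NumericMatrix delta(n, K);
  IntegerMatrix psi(n, K);
  NumericMatrix ltr(K, K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k)
      ltr(j, k) = std::log(trans(j, k));

  for (int k = 0; k < K; ++k)
    delta(0, k) = std::log(init[k]) + ldnorm(x[0], mu[k], sd[k]);
  for (int t = 1; t < n; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf; int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta(t - 1, j) + ltr(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + ldnorm(x[t], mu[k], sd[k]);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(n);
  double best = R_NegInf; int arg = 0;
  for (int k = 0; k < K; ++k) if (delta(n - 1, k) > best) { best = delta(n - 1, k); arg = k; }
  path[n - 1] = arg + 1;
  for (int t = n - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
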