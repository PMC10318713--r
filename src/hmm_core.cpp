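#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward pass for one observation sequence.
// logB: T x K matrix of per-state log observation densities.
// Returns loglik, posterior state probabilities (gamma), summed transition
// posteriors (xi, K x K) and the t=1 posterior (gamma1).
// [[Rcpp::export]]
List hmm_forward_backward(NumericMatrix logB, NumericVector init,
                          NumericMatrix trans) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix B(T, K), alpha(T, K), beta(T, K), gamma(T, K), xi(K, K);
  NumericVector mrow(T), ct(T);

  for (int t = 0; t < T; ++t) {
    double m = R_NegInf;
    for (int k = 0; k < K; ++k) if (logB(t, k) > m) m = logB(t, k);
    mrow[t] = m;
    for (int k = 0; k < K; ++k)
      B(t, k) = R_FINITE(m) ? std::exp(logB(t, k) - m) : 0.0;
  }

  // forward
  double c0 = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = init[k] * B(0, k); c0 += alpha(0, k); }
  if (!(c0 > 0)) return List::create(_["loglik"] = R_NegInf);
  ct[0] = c0;
  for (int k = 0; k < K; ++k) alpha(0, k) /= c0;
  for (int t = 1; t < T; ++t) {
    double cs = 0.0;
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int i = 0; i < K; ++i) s += alpha(t - 1, i) * trans(i, j);
      alpha(t, j) = s * B(t, j);
      cs += alpha(t, j);
    }
    if (!(cs > 0)) return List::create(_["loglik"] = R_NegInf);
    ct[t] = cs;
    for (int j = 0; j < K; ++j) alpha(t, j) /= cs;
  }
  double loglik = 0.0;
  for (int t = 0; t < T; ++t) loglik += std::log(ct[t]) + mrow[t];

  // backward
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += trans(i, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, i) = s / ct[t + 1];
    }
  }

  for (int t = 0; t < T; ++t) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); s += gamma(t, k); }
    if (s > 0) for (int k = 0; k < K; ++k) gamma(t, k) /= s;
  }

  for (int t = 0; t < T - 1; ++t) {
    for (int i = 0; i < K; ++i) {
      const double ai = alpha(t, i);
      for (int j = 0; j < K; ++j)
        xi(i, j) += ai * trans(i, j) * B(t + 1, j) * beta(t + 1, j) / ct[t + 1];
    }
  }

  NumericVector gamma1(K);
  for (int k = 0; k < K; ++k) gamma1[k] = gamma(0, k);
  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xi"] = xi, _["gamma1"] = gamma1);
}

// Log-space Viterbi. Ties break toward the lower state index (strict
// inequality when scanning candidates in increasing order).
// [[Rcpp::export]]
IntegerVector hmm_viterbi_path(NumericMatrix logB, NumericVector loginit,
                               NumericMatrix logtrans) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) delta(0, k) = loginit[k] + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = R_NegInf; int arg = 0;
      for (int i = 0; i < K; ++i) {
        double v = delta(t - 1, i) + logtrans(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + logB(t, j);
      psi(t, j) = arg;
    }
  }
  double best = R_NegInf; int arg = 0;
  for (int k = 0; k < K; ++k) if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  if (!R_FINITE(best)) stop("observation sequence has zero probability under every state");
  IntegerVector path(T);
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
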