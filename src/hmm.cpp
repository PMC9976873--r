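#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward pass for a Gaussian-emission HMM.
// Returns the log-likelihood, per-frame posteriors (gamma) and the
// summed transition posteriors (xi) needed by the Baum-Welch M-step.
// [[Rcpp::export]]
List hmm_forward_backward(NumericVector x, NumericVector mu,
                          NumericVector sigma, NumericMatrix A,
                          NumericVector pi0) {
  const int T = x.size(), K = mu.size();
  NumericMatrix B(T, K);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k)
      B(t, k) = R::dnorm(x[t], mu[k], sigma[k], 0) + 1e-300;

  NumericMatrix alpha(T, K), beta(T, K);
  NumericVector c(T);
  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi0[k] * B(0, k); s += alpha(0, k); }
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
      alpha(t, k) = a * B(t, k);
      s += alpha(t, k);
    }
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t)
    for (int k = 0; k < K; ++k) {
      double b = 0.0;
      for (int j = 0; j < K; ++j) b += A(k, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, k) = b / c[t + 1];
    }

  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }

  NumericMatrix xi(K, K);
  for (int t = 0; t < T - 1; ++t) {
    const double denom = c[t + 1];
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi(j, k) += alpha(t, j) * A(j, k) * B(t + 1, k) * beta(t + 1, k) / denom;
  }

  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(c[t]);
  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi"] = xi);
}

// Most-likely state path (Viterbi) in log space; 1-based states.
// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericVector x, NumericVector mu,
                          NumericVector sigma, NumericMatrix A,
                          NumericVector pi0) {
  const int T = x.size(), K = mu.size();
  NumericMatrix logB(T, K), V(T, K);
  IntegerMatrix back(T, K);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k)
      logB(t, k) = R::dnorm(x[t], mu[k], sigma[k], 1);
  NumericMatrix logA(K, K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k)
      logA(j, k) = std::log(A(j, k) + 1e-300);
  for (int k = 0; k < K; ++k)
    V(0, k) = std::log(pi0[k] + 1e-300) + logB(0, k);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf; int arg = 0;
      for (int j = 0; j < K; ++j) {
        const double v = V(t - 1, j) + logA(j, k);
        if (v > best) { best = v; arg = j; }
      }
      V(t, k) = best + logB(t, k);
      back(t, k) = arg;
    }
  IntegerVector path(T);
  double best = R_NegInf; int arg = 0;
  for (int k = 0; k < K; ++k)
    if (V(T - 1, k) > best) { best = V(T - 1, k); arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 1; t > 0; --t) {
    arg = back(t, arg);
    path[t - 1] = arg + 1;
  }
  return path;
}
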