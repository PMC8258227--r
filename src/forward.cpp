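#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward recursion for a discrete-time HMM.
// probs: n x m matrix of per-observation emission probabilities by state
// Gamma: m x m transition matrix (rows sum to 1)
// delta: initial state distribution
// Returns the log-likelihood; -Inf if the likelihood underflows to zero.
// [[Rcpp::export]]
double hmm_forward_cpp(NumericMatrix probs, NumericMatrix Gamma,
                       NumericVector delta) {
  int n = probs.nrow(), m = probs.ncol();
  std::vector<double> phi(m), psi(m);
  double ll = 0.0;
  for (int j = 0; j < m; ++j) phi[j] = delta[j] * probs(0, j);
  double c0 = 0.0;
  for (int j = 0; j < m; ++j) c0 += phi[j];
  if (c0 <= 0.0 || !R_finite(c0)) return R_NegInf;
  for (int j = 0; j < m; ++j) phi[j] /= c0;
  ll += std::log(c0);
  for (int t = 1; t < n; ++t) {
    double c = 0.0;
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int i = 0; i < m; ++i) s += phi[i] * Gamma(i, j);
      psi[j] = s * probs(t, j);
      c += psi[j];
    }
    if (c <= 0.0 || !R_finite(c)) return R_NegInf;
    for (int j = 0; j < m; ++j) phi[j] = psi[j] / c;
    ll += std::log(c);
  }
  return ll;
}
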