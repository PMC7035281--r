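#include <Rcpp.h>
using namespace Rcpp;

// Log-space Viterbi decoding with Gaussian emissions and fixed state means.
// Ties in the maximization are broken toward the lowest state index (strict
// inequality when scanning upward), which makes decoding deterministic.
// [[Rcpp::export]]
IntegerVector viterbi_gauss_cpp(NumericVector x, NumericVector means,
                                double sigma, NumericMatrix logA,
                                NumericVector logpi) {
  const int n = x.size(), ns = means.size();
  if (n == 0) return IntegerVector(0);
  NumericMatrix delta(ns, n);
  IntegerMatrix psi(ns, n);
  const double c0 = -0.5 * std::log(2.0 * M_PI) - std::log(sigma);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);

  for (int s = 0; s < ns; ++s) {
    double r = x[0] - means[s];
    delta(s, 0) = logpi[s] + c0 - r * r * inv2s2;
  }
  for (int t = 1; t < n; ++t) {
    for (int s = 0; s < ns; ++s) {
      double best = delta(0, t - 1) + logA(0, s);
      int arg = 0;
      for (int k = 1; k < ns; ++k) {
        double v = delta(k, t - 1) + logA(k, s);
        if (v > best) { best = v; arg = k; }
      }
      double r = x[t] - means[s];
      delta(s, t) = best + c0 - r * r * inv2s2;
      psi(s, t) = arg;
    }
  }
  IntegerVector path(n);
  double best = delta(0, n - 1);
  int arg = 0;
  for (int k = 1; k < ns; ++k)
    if (delta(k, n - 1) > best) { best = delta(k, n - 1); arg = k; }
  path[n - 1] = arg;
  for (int t = n - 1; t > 0; --t) path[t - 1] = psi(path[t], t);
  for (int t = 0; t < n; ++t) path[t] += 1;
  path.attr("loglik") = best;
  return path;
}
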