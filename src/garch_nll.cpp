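#include <Rcpp.h>
using namespace Rcpp;

// Negative Gaussian log-likelihood of an AR(ar_order in {0,1}) mean with
// GARCH(1,1) conditional variance, sigma^2_1 initialised at the
// unconditional variance omega / (1 - alpha - beta).  Called inside the
// optimiser's inner loop, hence compiled.
// [[Rcpp::export]]
double garch_nll_cpp(NumericVector x, double mu, double phi, double omega,
                     double alpha, double beta, int ar_order) {
  const double BIG = 1e10;
  if (!(omega > 0.0) || alpha < 0.0 || beta < 0.0 || alpha + beta >= 1.0)
    return BIG;
  const int n = x.size();
  const int m = ar_order == 1 ? n - 1 : n;
  if (m < 2) return BIG;

  const double log2pi = std::log(2.0 * M_PI);
  double s2 = omega / (1.0 - alpha - beta);
  double nll = 0.0;
  double e_prev = 0.0;
  for (int t = 0; t < m; ++t) {
    double e = ar_order == 1 ? x[t + 1] - mu - phi * x[t] : x[t] - mu;
    if (t > 0) s2 = omega + alpha * e_prev * e_prev + beta * s2;
    if (!(s2 > 0.0) || !std::isfinite(s2)) return BIG;
    nll += 0.5 * (log2pi + std::log(s2) + e * e / s2);
    e_prev = e;
  }
  return std::isfinite(nll) ? nll : BIG;
}
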