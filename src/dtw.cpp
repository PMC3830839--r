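#include <Rcpp.h>
using namespace Rcpp;

// Classic dynamic-time-warping distance with absolute-difference local
// cost, full window, boundary/monotonicity/continuity constraints.
// Two-row dynamic program, O(n*m) time, O(m) memory.
// [[Rcpp::export]]
double dtw_dist_cpp(NumericVector x, NumericVector y) {
  const int n = x.size(), m = y.size();
  std::vector<double> prev(m), curr(m);

  prev[0] = std::abs(x[0] - y[0]);
  for (int j = 1; j < m; ++j) prev[j] = prev[j - 1] + std::abs(x[0] - y[j]);

  for (int i = 1; i < n; ++i) {
    curr[0] = prev[0] + std::abs(x[i] - y[0]);
    for (int j = 1; j < m; ++j) {
      double best = std::min(prev[j], std::min(prev[j - 1], curr[j - 1]));
      curr[j] = best + std::abs(x[i] - y[j]);
    }
    std::swap(prev, curr);
  }
  return prev[m - 1];
}
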