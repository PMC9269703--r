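#include <Rcpp.h>
using namespace Rcpp;

// Pair counts for Sample Entropy (Richman & Moorman counting).
//
// Templates of length m and m+1 both start at positions 1..T where
// T = N - m (default) or N - m - 1 (drop_last). Distances are Chebyshev;
// a pair matches when distance <= r (leq = true) or < r. Self-matches are
// excluded by counting unordered pairs i < j only. Because the Chebyshev
// distance of the (m+1)-length extension can only grow, pairs failing at
// length m are skipped early.
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r,
                                bool leq, bool drop_last) {
  const int N = x.size();
  const int T = N - m - (drop_last ? 1 : 0);
  if (T < 2) return NumericVector::create(NA_REAL, NA_REAL);
  double A = 0.0, B = 0.0;
  for (int i = 0; i < T - 1; ++i) {
    for (int j = i + 1; j < T; ++j) {
      double d = 0.0;
      bool fail = false;
      for (int k = 0; k < m; ++k) {
        double dk = std::abs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
        if (leq ? (d > r) : (d >= r)) { fail = true; break; }
      }
      if (fail) continue;
      B += 1.0;
      double dm = std::abs(x[i + m] - x[j + m]);
      if (dm > d) d = dm;
      if (leq ? (d <= r) : (d < r)) A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}
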