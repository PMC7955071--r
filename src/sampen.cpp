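#include <Rcpp.h>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// Template match counts for sample entropy.
//
// Templates of length m and m+1 are both drawn from start indices
// 1..N-m so that the two counts are over the same index set (the
// Richman-Moorman convention). Matches use the Chebyshev (max-abs)
// distance with radius r; self-matches are excluded by counting each
// unordered pair of distinct templates once. Returns the pair counts
// A (length m+1) and B (length m); SampEn = -log(A/B).
//
// A Chebyshev match requires every coordinate pair within r, so
// candidate pairs are enumerated from a sort on the first template
// coordinate and only neighbors within r on that coordinate are
// examined; the counts are identical to the full O(N^2) scan.
//
// [[Rcpp::export]]
List sampen_counts(NumericVector x, int m, double r) {
  const int N = x.size();
  if (N < m + 2) stop("series too short: need length >= m + 2");
  const int nt = N - m;  // number of templates at both lengths
  std::vector<int> idx(nt);
  std::iota(idx.begin(), idx.end(), 0);
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  double A = 0.0, B = 0.0;
  for (int a = 0; a < nt - 1; ++a) {
    const int i = idx[a];
    for (int b = a + 1; b < nt && x[idx[b]] - x[i] <= r; ++b) {
      const int j = idx[b];
      double d = x[idx[b]] - x[i];
      for (int k = 1; k < m; ++k) {
        double t = std::abs(x[i + k] - x[j + k]);
        if (t > d) {
          d = t;
          if (d > r) break;  // Chebyshev distance can only grow
        }
      }
      if (d <= r) {
        B += 1.0;
        double t = std::abs(x[i + m] - x[j + m]);
        if (t <= r) A += 1.0;
      }
    }
  }
  return List::create(_["A"] = A, _["B"] = B, _["n_templates"] = nt);
}
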