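#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Template-match counts for sample entropy.
//
// B = number of unordered pairs (i, j), i != j, of m-length templates
//     whose Chebyshev distance is <= r (self-matches excluded);
// A = the same for (m+1)-length templates.
// Both counts range over i, j in [0, n - m - 1] so that every m-template
// that is counted can also be extended to length m + 1.
//
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // number of extensible templates
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::abs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (match) {
        B += 1.0;
        if (std::abs(x[i + m] - x[j + m]) <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}
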