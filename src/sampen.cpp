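#include <Rcpp.h>
using namespace Rcpp;

// Ordered-pair template match counts for sample entropy.
// B: pairs i != j, i, j <= N - m, with Chebyshev distance between the
//    length-m templates starting at i and j within r.
// A: same for length m + 1 templates, i, j <= N - m - 1.
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nb = n - m;      // number of length-m templates counted in B
  const int na = n - m - 1;  // number of length-(m+1) templates
  double B = 0.0, A = 0.0;
  for (int i = 0; i < nb; ++i) {
    for (int j = 0; j < nb; ++j) {
      if (i == j) continue;
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (!match) continue;
      B += 1.0;
      if (i < na && j < na && std::fabs(x[i + m] - x[j + m]) <= r)
        A += 1.0;
    }
  }
  return NumericVector::create(B, A);
}
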