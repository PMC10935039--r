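#include <Rcpp.h>
using namespace Rcpp;

// Approximate entropy by direct Chebyshev template matching.
// Self-matches are counted (i == j), so every C(i) >= 1 and the
// log-frequencies are always defined for r > 0.
// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  int N = x.size();
  double phi[2] = {0.0, 0.0};
  for (int dim = 0; dim < 2; ++dim) {
    int mm = m + dim;
    int n = N - mm + 1;
    if (n <= 0) return NA_REAL;
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      int count = 0;
      for (int j = 0; j < n; ++j) {
        double d = 0.0;
        for (int k = 0; k < mm; ++k) {
          double diff = std::fabs(x[i + k] - x[j + k]);
          if (diff > d) d = diff;
          if (d >= r) break;
        }
        if (d < r) ++count;
      }
      acc += std::log((double)count / (double)n);
    }
    phi[dim] = acc / (double)n;
  }
  double ap = phi[0] - phi[1];
  return ap < 0.0 ? 0.0 : ap;
}

// Template-match counts for sample entropy: number of pairs i < j whose
// embedded vectors stay within r (Chebyshev) at dimension m (B) and at
// dimension m + 1 (A). Self-matches excluded by construction. Both counts
// use the same N - m template positions so A/B is a proper conditional
// probability estimate.
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  int N = x.size();
  int n = N - m;
  double A = 0.0, B = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double diff = std::fabs(x[i + k] - x[j + k]);
        if (diff > d) d = diff;
        if (d >= r) break;
      }
      if (d < r) {
        B += 1.0;
        if (std::fabs(x[i + m] - x[j + m]) < r) A += 1.0;
      }
    }
  }
  return NumericVector::create(B, A);
}

// Lempel-Ziv (LZ76) parse count of a binary sequence.
// [[Rcpp::export]]
int lz76_cpp(IntegerVector s) {
  int n = s.size();
  if (n == 0) return 0;
  int c = 1;       // complexity counter, first symbol is the first word
  int i = 0;       // start of the current prefix already parsed
  int k = 1;       // length of the current candidate extension
  int k_max = 1;
  int j = 1;       // start of the current word being parsed
  while (j + k <= n) {
    if (s[i + k - 1] == s[j + k - 1]) {
      ++k;
      if (j + k > n) { ++c; break; }
    } else {
      if (k > k_max) k_max = k;
      ++i;
      if (i == j) {          // no prefix reproduces the word: new word
        ++c;
        j += k_max;
        i = 0;
        k = 1;
        k_max = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}
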