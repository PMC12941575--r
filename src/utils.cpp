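#include <Rcpp.h>
#include <cstdint>
#include <string>

using namespace Rcpp;

// 32-bit FNV-1a over the concatenated string parts; folded to [0, 2^31 - 1]
// so the result is always a valid R integer seed.
// [[Rcpp::export]]
int cpp_hash_seed(CharacterVector parts) {
  uint32_t h = 2166136261u;
  for (R_xlen_t i = 0; i < parts.size(); ++i) {
    std::string s = as<std::string>(parts[i]);
    for (char c : s) {
      h ^= static_cast<uint8_t>(c);
      h *= 16777619u;
    }
    h ^= 0x1fu;  // part separator so c("ab","c") != c("a","bc")
    h *= 16777619u;
  }
  return static_cast<int>(h & 0x7fffffffu);
}

// Template-match counts for sample entropy under Chebyshev distance.
// Both m- and (m+1)-length templates are anchored at i = 0 .. N-m-1 so the
// two counts are comparable (self-matches excluded, unordered pairs).
// Returns c(A, B): A = matches of length m+1, B = matches of length m.
// [[Rcpp::export]]
NumericVector cpp_sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // number of anchored templates
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
      }
      if (d <= r) {
        B += 1.0;
        if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}
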