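#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Weighted Levenshtein distance by two-row dynamic programming.
// Converting a -> b: deleting a character of `a` costs `del`, inserting a
// character of `b` costs `ins`, replacing one costs `sub`.
static double lev_dp(const std::string& a, const std::string& b,
                     double ins, double del, double sub) {
  const size_t n = a.size(), m = b.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  for (size_t j = 0; j <= m; ++j) prev[j] = j * ins;
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = i * del;
    for (size_t j = 1; j <= m; ++j) {
      double match = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0.0 : sub);
      cur[j] = std::min(match, std::min(prev[j] + del, cur[j - 1] + ins));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
double lev_distance_cpp(std::string a, std::string b,
                        double ins, double del, double sub) {
  return lev_dp(a, b, ins, del, sub);
}

// Pairwise distance matrix; only the upper triangle is computed, then mirrored.
// [[Rcpp::export]]
NumericMatrix lev_distance_matrix_cpp(CharacterVector seqs,
                                      double ins, double del, double sub) {
  const int n = seqs.size();
  NumericMatrix out(n, n);
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = lev_dp(s[i], s[j], ins, del, sub);
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}
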