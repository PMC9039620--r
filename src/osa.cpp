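#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Optimal string alignment (restricted Damerau-Levenshtein) distance:
// unit-cost deletion, insertion, substitution and adjacent transposition,
// with no further edits inside a transposed pair. Two rolling rows plus the
// row before them carry the transposition lookback.
static int osa_dist(const std::string &a, const std::string &b) {
  const int la = (int)a.size(), lb = (int)b.size();
  if (la == 0) return lb;
  if (lb == 0) return la;
  std::vector<int> prev2(lb + 1), prev(lb + 1), cur(lb + 1);
  for (int j = 0; j <= lb; ++j) prev[j] = j;
  for (int i = 1; i <= la; ++i) {
    cur[0] = i;
    for (int j = 1; j <= lb; ++j) {
      int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
      int d = std::min(std::min(prev[j] + 1, cur[j - 1] + 1),
                       prev[j - 1] + cost);
      if (i > 1 && j > 1 && a[i - 1] == b[j - 2] && a[i - 2] == b[j - 1])
        d = std::min(d, prev2[j - 2] + 1);
      cur[j] = d;
    }
    std::swap(prev2, prev);
    std::swap(prev, cur);
  }
  return prev[lb];
}

// [[Rcpp::export(name = ".osa_distance_cpp")]]
IntegerVector osa_distance_cpp(CharacterVector a, CharacterVector b) {
  if (a.size() != b.size()) stop("a and b must have equal length");
  IntegerVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i)
    out[i] = osa_dist(as<std::string>(a[i]), as<std::string>(b[i]));
  return out;
}

// Full pairwise distance matrix between two term vectors.
// [[Rcpp::export(name = ".osa_matrix_cpp")]]
IntegerMatrix osa_matrix_cpp(CharacterVector a, CharacterVector b) {
  IntegerMatrix out(a.size(), b.size());
  std::vector<std::string> bs(b.size());
  for (R_xlen_t j = 0; j < b.size(); ++j) bs[j] = as<std::string>(b[j]);
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    std::string ai = as<std::string>(a[i]);
    for (R_xlen_t j = 0; j < b.size(); ++j)
      out(i, j) = osa_dist(ai, bs[j]);
  }
  return out;
}
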