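#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// Classic two-row dynamic-programming edit distance
// (insert / delete / substitute, all unit cost).
static int lev_one(const std::string &a, const std::string &b) {
  const size_t n = a.size(), m = b.size();
  if (n == 0) return (int)m;
  if (m == 0) return (int)n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (size_t j = 0; j <= m; ++j) prev[j] = (int)j;
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = (int)i;
    for (size_t j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min(std::min(prev[j] + 1, cur[j - 1] + 1), sub);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export(name = ".lev_dist_cpp")]]
IntegerVector lev_dist_cpp(CharacterVector a, CharacterVector b) {
  R_xlen_t na = a.size(), nb = b.size();
  R_xlen_t n = std::max(na, nb);
  IntegerVector out(n);
  for (R_xlen_t k = 0; k < n; ++k) {
    if (CharacterVector::is_na(a[k % na]) || CharacterVector::is_na(b[k % nb])) {
      out[k] = NA_INTEGER;
      continue;
    }
    std::string sa = as<std::string>(a[k % na]);
    std::string sb = as<std::string>(b[k % nb]);
    out[k] = lev_one(sa, sb);
  }
  return out;
}
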