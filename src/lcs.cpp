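#include <Rcpp.h>
using namespace Rcpp;

// Longest common substring between a and b by O(n*m) dynamic programming.
// Returns c(length, start_a, start_b), 1-based starts (0 if no common char).
// Ties resolved toward the smallest (start_a, start_b) reached first in the
// row-major sweep, so results are deterministic.
// [[Rcpp::export]]
IntegerVector lcs_substring(const std::string& a, const std::string& b) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int best = 0, enda = 0, endb = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      cur[j] = (a[i - 1] == b[j - 1]) ? prev[j - 1] + 1 : 0;
      if (cur[j] > best) { best = cur[j]; enda = i; endb = j; }
    }
    std::swap(prev, cur);
  }
  return IntegerVector::create(best,
                               best ? enda - best + 1 : 0,
                               best ? endb - best + 1 : 0);
}

// Longest exact overlap between the 3' end (suffix) of a and the 5' end
// (prefix) of b, searched from the longest possible overlap down to
// min_overlap. Returns the overlap length, 0 if none reaches min_overlap.
// [[Rcpp::export]]
int suffix_prefix_overlap(const std::string& a, const std::string& b,
                          int min_overlap) {
  const int n = a.size(), m = b.size();
  int mx = std::min(n, m);
  for (int o = mx; o >= min_overlap; --o) {
    if (a.compare(n - o, o, b, 0, o) == 0) return o;
  }
  return 0;
}

// Vectorized reverse complement (full IUPAC alphabet; case preserved).
// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  static char comp[256];
  static bool init = false;
  if (!init) {
    for (int i = 0; i < 256; ++i) comp[i] = (char) i;
    const char* from = "ACGTRYSWKMBDHVNacgtryswkmbdhvn";
    const char* to   = "TGCAYRSWMKVHDBNtgcayrswmkvhdbn";
    for (int i = 0; from[i]; ++i) comp[(unsigned char) from[i]] = to[i];
    init = true;
  }
  int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    if (x[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    std::string s = as<std::string>(x[i]);
    std::string r(s.rbegin(), s.rend());
    for (size_t j = 0; j < r.size(); ++j) r[j] = comp[(unsigned char) r[j]];
    out[i] = r;
  }
  return out;
}

// Hamming mismatch count between equal-length strings.
// [[Rcpp::export]]
int hamming_mm(const std::string& a, const std::string& b) {
  if (a.size() != b.size()) stop("hamming_mm: unequal lengths");
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i) if (a[i] != b[i]) ++d;
  return d;
}
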