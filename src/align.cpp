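#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Scores one column. 'N' is treated as a mismatch against every base,
// including another 'N', so ambiguous sequence never contributes positive score.
static inline int col_score(char x, char y, int match, int mismatch) {
  if (x == 'N' || y == 'N') return mismatch;
  return (x == y) ? match : mismatch;
}

// Needleman-Wunsch, linear gap penalty. Traceback tie-break is fixed:
// diagonal > up (gap in b) > left (gap in a), giving bit-reproducible output.
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b, int match, int mismatch, int gap) {
  const size_t n = a.size(), m = b.size();
  if ((double)(n + 1) * (double)(m + 1) > 3e8)
    stop("sequences too long for full dynamic-programming alignment");
  std::vector<int> H((n + 1) * (m + 1));
  const size_t W = m + 1;
  for (size_t j = 0; j <= m; ++j) H[j] = (int)j * gap;
  for (size_t i = 1; i <= n; ++i) {
    H[i * W] = (int)i * gap;
    const char ai = a[i - 1];
    for (size_t j = 1; j <= m; ++j) {
      int diag = H[(i - 1) * W + (j - 1)] + col_score(ai, b[j - 1], match, mismatch);
      int up   = H[(i - 1) * W + j] + gap;
      int left = H[i * W + (j - 1)] + gap;
      int best = diag;
      if (up > best) best = up;
      if (left > best) best = left;
      H[i * W + j] = best;
    }
  }
  std::string out_a, out_b;
  out_a.reserve(n + m); out_b.reserve(n + m);
  size_t i = n, j = m;
  while (i > 0 || j > 0) {
    int h = H[i * W + j];
    if (i > 0 && j > 0 &&
        h == H[(i - 1) * W + (j - 1)] + col_score(a[i - 1], b[j - 1], match, mismatch)) {
      out_a.push_back(a[i - 1]); out_b.push_back(b[j - 1]); --i; --j;
    } else if (i > 0 && h == H[(i - 1) * W + j] + gap) {
      out_a.push_back(a[i - 1]); out_b.push_back('-'); --i;
    } else {
      out_a.push_back('-'); out_b.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(out_a.begin(), out_a.end());
  std::reverse(out_b.begin(), out_b.end());
  return List::create(_["aligned_a"] = out_a, _["aligned_b"] = out_b,
                      _["score"] = H[n * W + m],
                      _["start_a"] = 0, _["end_a"] = (int)n,
                      _["start_b"] = 0, _["end_b"] = (int)m);
}

// Smith-Waterman, linear gap penalty. The maximal cell is the first one
// reached in row-major order (smallest end_a, then end_b) among ties.
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string a, std::string b, int match, int mismatch, int gap) {
  const size_t n = a.size(), m = b.size();
  if ((double)(n + 1) * (double)(m + 1) > 3e8)
    stop("sequences too long for full dynamic-programming alignment");
  std::vector<int> H((n + 1) * (m + 1), 0);
  const size_t W = m + 1;
  int best = 0; size_t bi = 0, bj = 0;
  for (size_t i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    for (size_t j = 1; j <= m; ++j) {
      int diag = H[(i - 1) * W + (j - 1)] + col_score(ai, b[j - 1], match, mismatch);
      int up   = H[(i - 1) * W + j] + gap;
      int left = H[i * W + (j - 1)] + gap;
      int h = diag;
      if (up > h) h = up;
      if (left > h) h = left;
      if (h < 0) h = 0;
      H[i * W + j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best == 0) {
    return List::create(_["aligned_a"] = "", _["aligned_b"] = "", _["score"] = 0,
                        _["start_a"] = 0, _["end_a"] = 0,
                        _["start_b"] = 0, _["end_b"] = 0);
  }
  std::string out_a, out_b;
  size_t i = bi, j = bj;
  while (i > 0 && j > 0 && H[i * W + j] > 0) {
    int h = H[i * W + j];
    if (h == H[(i - 1) * W + (j - 1)] + col_score(a[i - 1], b[j - 1], match, mismatch)) {
      out_a.push_back(a[i - 1]); out_b.push_back(b[j - 1]); --i; --j;
    } else if (i > 0 && h == H[(i - 1) * W + j] + gap) {
      out_a.push_back(a[i - 1]); out_b.push_back('-'); --i;
    } else {
      out_a.push_back('-'); out_b.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(out_a.begin(), out_a.end());
  std::reverse(out_b.begin(), out_b.end());
  return List::create(_["aligned_a"] = out_a, _["aligned_b"] = out_b,
                      _["score"] = best,
                      _["start_a"] = (int)i, _["end_a"] = (int)bi,
                      _["start_b"] = (int)j, _["end_b"] = (int)bj);
}

// Sliding ungapped identity of a probe against every start position of a
// subject: out[i] = number of matching bases of probe laid at subject[i..].
// Used for phase-anchor detection in monomer extraction.
// [[Rcpp::export(name = ".probe_scan_cpp")]]
IntegerVector probe_scan_cpp(std::string subject, std::string probe) {
  const size_t n = subject.size(), w = probe.size();
  if (n < w) return IntegerVector(0);
  IntegerVector out(n - w + 1);
  for (size_t i = 0; i + w <= n; ++i) {
    int s = 0;
    for (size_t j = 0; j < w; ++j)
      if (subject[i + j] == probe[j] && probe[j] != 'N') ++s;
    out[i] = s;
  }
  return out;
}
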