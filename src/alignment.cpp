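#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>

using namespace Rcpp;

// Semi-global alignment: `pattern` is aligned end-to-end, gaps at either end
// of `text` are free (unit edit costs). Used to locate short indexes/primers
// inside a read window. Ties are resolved to the smallest start, then the
// smallest end, so results are reproducible across platforms.
//
// Returns c(edits, start, end) with 0-based half-open [start, end) in text.
// [[Rcpp::export]]
IntegerVector cpp_semiglobal_fit(std::string pattern, std::string text) {
  const int m = pattern.size(), n = text.size();
  if (m == 0) stop("pattern must be non-empty");
  std::vector<int> prev(n + 1), cur(n + 1);
  // full matrix kept for traceback; (m+1) x (n+1) ints is small for our uses
  std::vector<int> dp((m + 1) * (n + 1));
  for (int j = 0; j <= n; ++j) dp[j] = 0;
  for (int i = 1; i <= m; ++i) {
    dp[i * (n + 1)] = i;
    for (int j = 1; j <= n; ++j) {
      int diag = dp[(i - 1) * (n + 1) + (j - 1)] + (pattern[i - 1] == text[j - 1] ? 0 : 1);
      int up   = dp[(i - 1) * (n + 1) + j] + 1;      // gap in text
      int left = dp[i * (n + 1) + (j - 1)] + 1;      // gap in pattern
      int v = diag < up ? diag : up;
      if (left < v) v = left;
      dp[i * (n + 1) + j] = v;
    }
  }
  int best = std::numeric_limits<int>::max();
  for (int j = 0; j <= n; ++j) best = std::min(best, dp[m * (n + 1) + j]);
  int best_start = -1, best_end = -1;
  for (int j = 0; j <= n; ++j) {
    if (dp[m * (n + 1) + j] != best) continue;
    // traceback from (m, j) preferring diagonal, then pattern-gap, then text-gap
    int i = m, jj = j;
    while (i > 0 && jj > 0) {
      int here = dp[i * (n + 1) + jj];
      int diag = dp[(i - 1) * (n + 1) + (jj - 1)] + (pattern[i - 1] == text[jj - 1] ? 0 : 1);
      if (diag == here) { --i; --jj; continue; }
      if (dp[i * (n + 1) + (jj - 1)] + 1 == here) { --jj; continue; }
      --i;
    }
    int start = jj;
    if (best_start == -1 || start < best_start ||
        (start == best_start && j < best_end)) {
      best_start = start;
      best_end = j;
    }
  }
  return IntegerVector::create(best, best_start, best_end);
}

// Global alignment with free end gaps on both sequences ("overlap" style,
// cd-hit-like identity semantics). End gaps cost nothing in the score but the
// returned gapped strings cover both sequences completely, so identity
// computed as matches / alignment_length counts unaligned overhangs against
// the pair.
// [[Rcpp::export]]
List cpp_overlap_align(std::string a, std::string b,
                       int match = 2, int mismatch = -4, int gap = -6) {
  const int m = a.size(), n = b.size();
  if (m == 0 || n == 0) stop("sequences must be non-empty");
  std::vector<int> dp((m + 1) * (n + 1));
  const int W = n + 1;
  for (int j = 0; j <= n; ++j) dp[j] = 0;
  for (int i = 1; i <= m; ++i) {
    dp[i * W] = 0;
    for (int j = 1; j <= n; ++j) {
      int diag = dp[(i - 1) * W + (j - 1)] + (a[i - 1] == b[j - 1] ? match : mismatch);
      int up   = dp[(i - 1) * W + j] + gap;
      int left = dp[i * W + (j - 1)] + gap;
      int v = diag > up ? diag : up;
      if (left > v) v = left;
      dp[i * W + j] = v;
    }
  }
  // best end on last row or last column (free trailing gaps)
  int bi = m, bj = n, best = dp[m * W + n];
  for (int j = 0; j <= n; ++j)
    if (dp[m * W + j] > best) { best = dp[m * W + j]; bi = m; bj = j; }
  for (int i = 0; i <= m; ++i)
    if (dp[i * W + n] > best) { best = dp[i * W + n]; bi = i; bj = n; }

  std::string ag, bg;
  // trailing overhang
  for (int i = m; i > bi; --i) { ag.push_back(a[i - 1]); bg.push_back('-'); }
  for (int j = n; j > bj; --j) { ag.push_back('-'); bg.push_back(b[j - 1]); }
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    int here = dp[i * W + j];
    int diag = dp[(i - 1) * W + (j - 1)] + (a[i - 1] == b[j - 1] ? match : mismatch);
    if (diag == here) {
      ag.push_back(a[i - 1]); bg.push_back(b[j - 1]); --i; --j;
    } else if (dp[(i - 1) * W + j] + gap == here) {
      ag.push_back(a[i - 1]); bg.push_back('-'); --i;
    } else {
      ag.push_back('-'); bg.push_back(b[j - 1]); --j;
    }
  }
  // leading overhang
  while (i > 0) { ag.push_back(a[i - 1]); bg.push_back('-'); --i; }
  while (j > 0) { ag.push_back('-'); bg.push_back(b[j - 1]); --j; }
  std::reverse(ag.begin(), ag.end());
  std::reverse(bg.begin(), bg.end());

  int matches = 0;
  for (size_t k = 0; k < ag.size(); ++k)
    if (ag[k] == bg[k] && ag[k] != '-') ++matches;
  return List::create(_["score"] = best,
                      _["matches"] = matches,
                      _["aln_len"] = (int) ag.size(),
                      _["a_gap"] = ag,
                      _["b_gap"] = bg);
}
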