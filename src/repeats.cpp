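#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// A/C/G/T -> 0..3, anything else (N, IUPAC ambiguity) -> -1: degenerate
// bases never match anything.
static inline int code(char ch) {
  switch (ch) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

static inline int comp(int c) { return c < 0 ? -1 : 3 - c; }

// Enumerate maximal repeat hits.
//
// A hit (arm1 at i, arm2, length len) is valid when: both arm endpoints
// match, at most max_mismatch internal substitutions, no degenerate base
// inside either arm, min_arm <= len <= max_arm, arms do not overlap, and
// the spacer between them is <= max_spacer. A valid hit is reported unless
// another valid hit on the same pairing diagonal strictly contains it.
// For direct repeats the diagonal is the offset d = arm2_start - arm1_start;
// for inverted repeats it is the coordinate sum c = arm1_start + arm2_end
// (arm2 is the reverse complement of arm1).
// [[Rcpp::export]]
DataFrame scan_repeats_cpp(std::string seq, int min_arm, int max_mismatch,
                           int max_spacer, int max_arm, bool inverted) {
  int n = (int) seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = code(seq[i]);
  std::vector<int> a1s, a1e, a2s, a2e, alen, mm, spc;

  if (!inverted) {
    int dmax = std::min(n - 1, max_arm + max_spacer);
    for (int d = min_arm; d <= dmax; ++d) {
      int lenmin = std::max(min_arm, d - max_spacer);
      long maxend = -1;
      for (int i = 0; i + d < n; ++i) {
        int x0 = s[i], y0 = s[i + d];
        if (x0 < 0 || y0 < 0 || x0 != y0) continue;
        int cap = std::min(d, std::min(max_arm, n - d - i));
        int mis = 0, best = -1, bestmm = 0;
        for (int t = 0; t < cap; ++t) {
          int x = s[i + t], y = s[i + d + t];
          if (x < 0 || y < 0) break;
          if (x != y) {
            if (++mis > max_mismatch) break;
            continue;
          }
          int len = t + 1;
          if (len >= lenmin) { best = len; bestmm = mis; }
        }
        if (best < 0) continue;
        long end = (long) i + best - 1;
        if (end <= maxend) continue; // contained in an earlier hit
        maxend = end;
        a1s.push_back(i + 1); a1e.push_back(i + best);
        a2s.push_back(i + d + 1); a2e.push_back(i + d + best);
        alen.push_back(best); mm.push_back(bestmm); spc.push_back(d - best);
      }
    }
  } else {
    int spanmax = std::min(2 * max_arm + max_spacer, n);
    for (int c = 2 * min_arm - 1; c <= 2 * n - 2; ++c) {
      int ilo = std::max(0, c - n + 1);
      int need = (int) std::ceil((c + 1.0 - spanmax) / 2.0);
      if (need > ilo) ilo = need;
      int ihi = (c + 1 - 2 * min_arm) / 2;
      long maxend = -1;
      for (int i = ilo; i <= ihi; ++i) {
        int e = c - i;
        if (e >= n) continue;
        int x0 = s[i], y0 = comp(s[e]);
        if (x0 < 0 || y0 < 0 || x0 != y0) continue;
        int span = e - i + 1;
        int cap = std::min(span / 2, max_arm);
        int lenmin = std::max(min_arm, (span - max_spacer + 1) / 2);
        int mis = 0, best = -1, bestmm = 0;
        for (int t = 0; t < cap; ++t) {
          int x = s[i + t], y = comp(s[e - t]);
          if (x < 0 || y < 0) break;
          if (x != y) {
            if (++mis > max_mismatch) break;
            continue;
          }
          int len = t + 1;
          if (len >= lenmin) { best = len; bestmm = mis; }
        }
        if (best < 0) continue;
        long end = (long) i + best - 1;
        if (end <= maxend) continue;
        maxend = end;
        a1s.push_back(i + 1); a1e.push_back(i + best);
        a2s.push_back(e - best + 2); a2e.push_back(e + 1);
        alen.push_back(best); mm.push_back(bestmm);
        spc.push_back(span - 2 * best);
      }
    }
  }

  return DataFrame::create(
    Named("arm1_start") = a1s, Named("arm1_end") = a1e,
    Named("arm2_start") = a2s, Named("arm2_end") = a2e,
    Named("arm_length") = alen, Named("mismatches") = mm,
    Named("spacer") = spc);
}
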