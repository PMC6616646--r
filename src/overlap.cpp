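#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive ungapped suffix-prefix/containment overlap between two sequences.
//
// Every relative placement of b against a is scored: offset is the 0-based
// start of b in a's coordinate frame (negative = b hangs off a's left end).
// For each offset the aligned columns are the positions covered by both
// sequences; identity = matching columns / aligned columns, with 'N' never
// matching anything. Among placements with overlap_len >= min_overlap and
// identity >= min_identity, the winner maximises (overlap_len, identity,
// then smallest offset). Identity ties are compared exactly with integer
// cross-multiplication, so the result is reproducible across platforms.
//
// [[Rcpp::export]]
List cpp_best_overlap(std::string a, std::string b,
                      int min_overlap, double min_identity) {
  const int la = (int)a.size(), lb = (int)b.size();
  int best_len = -1, best_match = -1, best_off = 0;
  bool found = false;
  for (int off = -(lb - 1); off <= la - 1; ++off) {
    const int lo = std::max(0, off);            // in a coordinates
    const int hi = std::min(la, off + lb);
    const int len = hi - lo;
    if (len < min_overlap) continue;
    int match = 0;
    for (int i = lo; i < hi; ++i) {
      const char ca = a[i], cb = b[i - off];
      if (ca == cb && ca != 'N') ++match;
    }
    if ((double)match + 1e-9 < min_identity * (double)len) continue;
    bool better;
    if (!found) {
      better = true;
    } else if (len != best_len) {
      better = len > best_len;
    } else {
      // identity tie-break without floating point: match/len vs best
      long long l = (long long)match * (long long)best_len;
      long long r = (long long)best_match * (long long)len;
      better = l > r;   // equal identity keeps the earlier (smaller) offset
    }
    if (better) {
      found = true;
      best_len = len; best_match = match; best_off = off;
    }
  }
  if (!found) return List::create();
  return List::create(
    _["offset"] = best_off,
    _["overlapLen"] = best_len,
    _["identity"] = (double)best_match / (double)best_len);
}

// Hamming distance between motif and subject at a given 1-based position;
// 'N' in the subject counts as a mismatch against any motif base.
// [[Rcpp::export]]
int cpp_mismatches_at(std::string subject, std::string motif, int at) {
  const int n = (int)motif.size();
  int mm = 0;
  for (int i = 0; i < n; ++i) {
    const char cs = subject[at - 1 + i];
    if (cs != motif[i] || cs == 'N') ++mm;
  }
  return mm;
}

// True if any ungapped placement of b against a contains a window of
// `win` aligned columns with at most `max_mm` mismatches ('N' mismatches
// everything). Used by the locus simulator as a separability screen:
// if every 30-column window at every offset has >= 3 mismatches, then no
// aligned window of ANY length L >= 30 can reach 95% identity
// (mismatches >= 3*floor(L/30) > 0.05*L for all L >= 30).
// [[Rcpp::export]]
bool cpp_has_nearmatch_window(std::string a, std::string b,
                              int win, int max_mm) {
  const int la = (int)a.size(), lb = (int)b.size();
  for (int off = -(lb - 1); off <= la - 1; ++off) {
    const int lo = std::max(0, off);
    const int hi = std::min(la, off + lb);
    const int len = hi - lo;
    if (len < win) continue;
    int mm = 0;
    for (int i = lo; i < hi; ++i) {
      const char ca = a[i], cb = b[i - off];
      const bool mis = (ca != cb) || ca == 'N' || cb == 'N';
      if (mis) ++mm;
      if (i - lo >= win) {
        const char pa = a[i - win], pb = b[i - win - off];
        if (pa != pb || pa == 'N' || pb == 'N') --mm;
      }
      if (i - lo >= win - 1 && mm <= max_mm) return true;
    }
  }
  return false;
}
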