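#include <Rcpp.h>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Leftmost 3' adapter start for each read.
//
// A position matches when the overlap between the read suffix and the
// adapter prefix is at least `min_overlap` nt and the Hamming distance over
// that overlap is <= 1 for overlaps >= `mm_min_overlap` nt, 0 otherwise.
// Returns 1-based match positions, 0 where no position matches.
// [[Rcpp::export]]
IntegerVector cpp_adapter_pos(CharacterVector seqs, std::string adapter,
                              int min_overlap = 7, int mm_min_overlap = 10) {
  int n = seqs.size();
  int alen = adapter.size();
  IntegerVector out(n);
  for (int r = 0; r < n; ++r) {
    if (seqs[r] == NA_STRING) { out[r] = NA_INTEGER; continue; }
    std::string s = as<std::string>(seqs[r]);
    int len = s.size();
    int pos = 0;
    for (int i = 0; i + min_overlap <= len; ++i) {
      int o = std::min(alen, len - i);
      int allowed = (o >= mm_min_overlap) ? 1 : 0;
      int mm = 0;
      for (int k = 0; k < o; ++k) {
        if (s[i + k] != adapter[k] && ++mm > allowed) break;
      }
      if (mm <= allowed) { pos = i + 1; break; }
    }
    out[r] = pos;
  }
  return out;
}

// Mean PHRED quality over the first `lens[i]` bases of each quality string.
// NaN for zero-length prefixes.
// [[Rcpp::export]]
NumericVector cpp_mean_qual(CharacterVector quals, IntegerVector lens,
                            int offset = 33) {
  int n = quals.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (quals[i] == NA_STRING) { out[i] = NA_REAL; continue; }
    const char *q = CHAR(STRING_ELT(quals, i));
    int len = lens[i];
    if (len <= 0) { out[i] = R_NaN; continue; }
    long sum = 0;
    for (int k = 0; k < len; ++k) sum += (int)(unsigned char)q[k] - offset;
    out[i] = (double)sum / len;
  }
  return out;
}

// Best ungapped placement of each tag against a mature miRNA catalog.
//
// Placement: the tag starts `off5` bases 3' of the mature 5' end and ends
// `off3` bases 3' of the mature 3' end (off3 = off5 + len(tag) - len(mature)).
// Both offsets are bounded by `max_off` and the overlap must cover at least
// len(mature) - 2 bases. Mismatches are the Hamming distance over the
// overlap plus one per overhang base that is not confirmed by the precursor
// flank (`flank5` = up to 2 bases immediately 5' of the mature in its
// precursor, `flank3` the 3' counterpart; empty when unknown).
//
// Matures must be supplied in the tie-break order (lexicographic name);
// the best hit minimizes (mismatches, |off5| + |off3|, mature index, off5).
// Returns idx (1-based, 0 = no hit), mm, off5, off3.
// [[Rcpp::export]]
List cpp_match_mirna(CharacterVector tags, CharacterVector matures,
                     CharacterVector flank5, CharacterVector flank3,
                     int max_mm = 2, int max_off = 2) {
  int n = tags.size(), m = matures.size();
  std::vector<std::string> mat(m), f5(m), f3(m);
  for (int j = 0; j < m; ++j) {
    mat[j] = as<std::string>(matures[j]);
    f5[j] = as<std::string>(flank5[j]);
    f3[j] = as<std::string>(flank3[j]);
  }
  IntegerVector best_idx(n), best_mm(n), best_o5(n), best_o3(n);
  for (int r = 0; r < n; ++r) {
    std::string tag = as<std::string>(tags[r]);
    int Lt = tag.size();
    int b_mm = max_mm + 1, b_sum = 0, b_j = -1, b_o5 = 0, b_o3 = 0;
    for (int j = 0; j < m; ++j) {
      int Lm = mat[j].size();
      if (std::abs(Lt - Lm) > 2 * max_off) continue;
      for (int o5 = -max_off; o5 <= max_off; ++o5) {
        int o3 = o5 + Lt - Lm;
        if (o3 < -max_off || o3 > max_off) continue;
        int lo = std::max(o5, 0);            // overlap in mature coords
        int hi = std::min(o5 + Lt, Lm);      // exclusive
        int overlap = hi - lo;
        if (overlap < Lm - 2) continue;
        int mm = 0;
        for (int k = lo; k < hi && mm <= max_mm; ++k)
          if (tag[k - o5] != mat[j][k]) ++mm;
        if (o5 < 0) {                        // 5' overhang of -o5 bases
          int n5 = (int)f5[j].size();
          for (int t = 1; t <= -o5 && mm <= max_mm; ++t) {
            // t-th base upstream of the mature 5' end
            char tb = tag[-o5 - t];
            if (t > n5 || f5[j][n5 - t] != tb) ++mm;
          }
        }
        if (o3 > 0) {                        // 3' overhang of o3 bases
          int n3 = (int)f3[j].size();
          for (int t = 1; t <= o3 && mm <= max_mm; ++t) {
            char tb = tag[Lt - o3 + t - 1];
            if (t > n3 || f3[j][t - 1] != tb) ++mm;
          }
        }
        if (mm > max_mm) continue;
        int osum = std::abs(o5) + std::abs(o3);
        if (mm < b_mm || (mm == b_mm && osum < b_sum)) {
          b_mm = mm; b_sum = osum; b_j = j; b_o5 = o5; b_o3 = o3;
        }
        // equal (mm, osum): earlier mature index / smaller off5 was seen
        // first, so strict inequality keeps the canonical winner
      }
    }
    if (b_j < 0) {
      best_idx[r] = 0; best_mm[r] = NA_INTEGER;
      best_o5[r] = NA_INTEGER; best_o3[r] = NA_INTEGER;
    } else {
      best_idx[r] = b_j + 1; best_mm[r] = b_mm;
      best_o5[r] = b_o5; best_o3[r] = b_o3;
    }
  }
  return List::create(_["idx"] = best_idx, _["mismatches"] = best_mm,
                      _["off5"] = best_o5, _["off3"] = best_o3);
}
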