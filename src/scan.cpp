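#include <Rcpp.h>
#include <set>
#include <tuple>
using namespace Rcpp;

// Seed-and-extend microsatellite scan over one sequence.
//
// A seed is >=3 exact tandem copies of a primitive motif (>=8 bases for 1-2 nt
// motifs). From each seed, extension proceeds base by base in both directions:
// +match_score for a base matching the expected phase base, -mismatch_penalty
// otherwise (N and any non-ACGT base never match). Extension terminates when a
// run of more than max_successive_mismatch consecutive mismatches occurs, or
// when the running score falls more than max_successive_mismatch *
// mismatch_penalty below its running maximum; the locus is then trimmed back
// to the farthest position attaining the maximal running score (so reported
// loci start and end on matching bases and never contain a mismatch run longer
// than the limit). Candidates are deduplicated on (start, end, phase-aligned
// motif); length/score filtering and overlap resolution happen in R.

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

static bool motif_primitive(const std::vector<int>& code, int p, int k) {
  for (int d = 1; d < k; ++d) {
    if (k % d != 0) continue;
    bool rep = true;
    for (int i = d; i < k && rep; ++i) {
      if (code[p + i] != code[p + i % d]) rep = false;
    }
    if (rep) return false;
  }
  return true;
}

// [[Rcpp::export]]
DataFrame scan_candidates_cpp(std::string seq, IntegerVector motif_lengths,
                              int max_successive_mismatch, int match_score,
                              int mismatch_penalty) {
  const int n = (int) seq.size();
  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) code[i] = base_code(seq[i]);

  const int drop_limit = max_successive_mismatch * mismatch_penalty;
  std::set<std::tuple<int, int, std::string> > seen;
  std::vector<int> out_start, out_end, out_mm, out_score;
  std::vector<std::string> out_motif;

  for (int ki = 0; ki < motif_lengths.size(); ++ki) {
    const int k = motif_lengths[ki];
    const int copies = (k == 1) ? 8 : (k == 2) ? 4 : 3;
    const int seedlen = k * copies;
    if (n < seedlen) continue;
    for (int p = 0; p + seedlen <= n; ++p) {
      bool ok = true;
      for (int i = 0; i < k && ok; ++i) if (code[p + i] < 0) ok = false;
      if (!ok) continue;
      for (int i = k; i < seedlen && ok; ++i) {
        if (code[p + i] < 0 || code[p + i] != code[p + i % k]) ok = false;
      }
      if (!ok) continue;
      if (!motif_primitive(code, p, k)) continue;

      // extend right from seed end
      int cum = 0, best = 0, run = 0, e = p + seedlen;
      for (int i = p + seedlen; i < n; ++i) {
        int exp = code[p + (i - p) % k];
        if (code[i] >= 0 && code[i] == exp) {
          cum += match_score; run = 0;
          if (cum >= best) { best = cum; e = i + 1; }
        } else {
          cum -= mismatch_penalty; ++run;
          if (run > max_successive_mismatch) break;
          if (cum < best - drop_limit) break;
        }
      }
      // extend left from seed start
      cum = 0; best = 0; run = 0;
      int s = p;
      for (int j = p - 1; j >= 0; --j) {
        int ph = ((j - p) % k + k) % k;
        int exp = code[p + ph];
        if (code[j] >= 0 && code[j] == exp) {
          cum += match_score; run = 0;
          if (cum >= best) { best = cum; s = j; }
        } else {
          cum -= mismatch_penalty; ++run;
          if (run > max_successive_mismatch) break;
          if (cum < best - drop_limit) break;
        }
      }

      // phase-aligned motif at s
      std::string motif0(k, 'N');
      int shift = ((s - p) % k + k) % k;
      static const char bases[4] = {'A', 'C', 'G', 'T'};
      for (int t = 0; t < k; ++t) motif0[t] = bases[code[p + (shift + t) % k]];

      int mm = 0;
      for (int i = s; i < e; ++i) {
        int exp = code[p + ((i - p) % k + k) % k];
        if (!(code[i] >= 0 && code[i] == exp)) ++mm;
      }
      int len = e - s;
      int score = (len - mm) * match_score - mm * mismatch_penalty;

      auto key = std::make_tuple(s, e, motif0);
      if (seen.insert(key).second) {
        out_start.push_back(s + 1);  // 1-based inclusive
        out_end.push_back(e);
        out_motif.push_back(motif0);
        out_mm.push_back(mm);
        out_score.push_back(score);
      }
    }
  }

  return DataFrame::create(
    _["start"] = out_start, _["end"] = out_end, _["motif"] = out_motif,
    _["mismatches"] = out_mm, _["score"] = out_score,
    _["stringsAsFactors"] = false);
}
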