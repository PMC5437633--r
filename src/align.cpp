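#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Ungapped seed-extend local search of query sequences against a subject
// genome. Exact-match seeds of `word_size` are located through a
// counting-sort word index of the subject; each seed is extended in both
// directions with X-drop termination and trimmed back to the maximal-score
// endpoints. Masked (non-ACGT) characters never match and act as hard stops,
// so no alignment column ever pairs a mask character with anything.
// High-scoring segment pairs (HSPs) are returned; clustering into hits and
// Karlin-Altschul E-values happen in R.

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
      case 'A': r[i] = 'T'; break; case 'C': r[i] = 'G'; break;
      case 'G': r[i] = 'C'; break; case 'T': r[i] = 'A'; break;
      default: break;
    }
  }
  return r;
}

// [[Rcpp::export]]
DataFrame seed_extend_search_cpp(CharacterVector queries,
                                 CharacterVector subject_chroms,
                                 int word_size, int match, int mismatch,
                                 int xdrop, int min_hsp_score, int max_bucket,
                                 bool both_strands) {
  // concatenate subject with one separator char between chromosomes
  std::string subj;
  std::vector<int> chrom_offset(subject_chroms.size());
  for (int c = 0; c < subject_chroms.size(); ++c) {
    chrom_offset[c] = (int) subj.size();
    subj += as<std::string>(subject_chroms[c]);
    if (c + 1 < subject_chroms.size()) subj += '~';
  }
  const int M = (int) subj.size();
  std::vector<int> scode(M);
  for (int i = 0; i < M; ++i) scode[i] = base_code(subj[i]);

  // rolling word codes over the subject
  const uint32_t nwords = 1u << (2 * word_size);
  const uint32_t wmask = nwords - 1;
  std::vector<int> wcode(M, -1);
  {
    uint32_t w = 0; int run = 0;
    for (int i = 0; i < M; ++i) {
      if (scode[i] < 0) { run = 0; w = 0; continue; }
      w = ((w << 2) | (uint32_t) scode[i]) & wmask;
      if (++run >= word_size) wcode[i - word_size + 1] = (int) w;
    }
  }
  // counting sort into buckets
  std::vector<int> counts(nwords + 1, 0);
  for (int i = 0; i < M; ++i) if (wcode[i] >= 0) ++counts[wcode[i] + 1];
  for (uint32_t w = 0; w < nwords; ++w) counts[w + 1] += counts[w];
  std::vector<int> bucket_pos(counts[nwords]);
  {
    std::vector<int> fill(counts.begin(), counts.end() - 1);
    for (int i = 0; i < M; ++i)
      if (wcode[i] >= 0) bucket_pos[fill[wcode[i]]++] = i;
  }

  std::vector<int> out_q, out_qs, out_qe, out_ss, out_se, out_mm, out_len, out_score;
  std::vector<int> out_strand;  // 1 = plus, -1 = minus

  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string qplus = as<std::string>(queries[qi]);
    const int qlen = (int) qplus.size();
    for (int strand = 0; strand < (both_strands ? 2 : 1); ++strand) {
      std::string q = strand == 0 ? qplus : revcomp_str(qplus);
      std::vector<int> qcode(qlen);
      for (int i = 0; i < qlen; ++i) qcode[i] = base_code(q[i]);
      std::unordered_map<long long, int> diag_cover;

      uint32_t w = 0; int run = 0;
      for (int qp = 0; qp < qlen; ++qp) {
        if (qcode[qp] < 0) { run = 0; w = 0; continue; }
        w = ((w << 2) | (uint32_t) qcode[qp]) & wmask;
        if (++run < word_size) continue;
        const int q0 = qp - word_size + 1;
        const int b0 = counts[w], b1 = counts[w + 1];
        if (b1 - b0 > max_bucket) continue;  // over-represented (repeat) word
        for (int bi = b0; bi < b1; ++bi) {
          const int s0 = bucket_pos[bi];
          const long long d = (long long) s0 - q0;
          auto it = diag_cover.find(d);
          if (it != diag_cover.end() && s0 < it->second) continue;

          // extend right from the end of the word
          int cum = word_size * match, best = cum;
          int qe = q0 + word_size, se = s0 + word_size;
          int i = qe, j = se;
          while (i < qlen && j < M) {
            if (qcode[i] < 0 || scode[j] < 0) break;
            cum += (qcode[i] == scode[j]) ? match : mismatch;
            ++i; ++j;
            if (cum >= best) { best = cum; qe = i; se = j; }
            else if (cum < best - xdrop) break;
          }
          int right_best = best;
          // extend left from the start of the word
          cum = 0; best = 0;
          int qs = q0, ss = s0;
          i = q0 - 1; j = s0 - 1;
          while (i >= 0 && j >= 0) {
            if (qcode[i] < 0 || scode[j] < 0) break;
            cum += (qcode[i] == scode[j]) ? match : mismatch;
            if (cum >= best) { best = cum; qs = i; ss = j; }
            else if (cum < best - xdrop) break;
            --i; --j;
          }
          const int score = right_best + best;
          const int len = qe - qs;
          diag_cover[d] = se;
          if (score < min_hsp_score) continue;
          int mm = 0;
          for (int t = 0; t < len; ++t) if (qcode[qs + t] != scode[ss + t]) ++mm;
          // report query coords on the original (plus) orientation, 1-based
          int oqs, oqe;
          if (strand == 0) { oqs = qs + 1; oqe = qe; }
          else { oqs = qlen - qe + 1; oqe = qlen - qs; }
          out_q.push_back(qi + 1);
          out_strand.push_back(strand == 0 ? 1 : -1);
          out_qs.push_back(oqs); out_qe.push_back(oqe);
          out_ss.push_back(ss + 1); out_se.push_back(ss + len);
          out_mm.push_back(mm); out_len.push_back(len);
          out_score.push_back(score);
        }
      }
    }
  }

  DataFrame hsps = DataFrame::create(
    _["query_idx"] = out_q, _["strand"] = out_strand,
    _["qstart"] = out_qs, _["qend"] = out_qe,
    _["sstart_global"] = out_ss, _["send_global"] = out_se,
    _["mismatches"] = out_mm, _["length"] = out_len, _["score"] = out_score,
    _["stringsAsFactors"] = false);
  hsps.attr("chrom_offset") = IntegerVector(chrom_offset.begin(), chrom_offset.end());
  hsps.attr("subject_total") = M;
  return hsps;
}
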