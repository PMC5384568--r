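// read preprocessing primitives: adapter clip positions, 3' quality trim
// lengths, and overlap merging of forward/reverse pairs.

#include "common.h"
#include <climits>
#include <cmath>

using namespace Rcpp;

// Leftmost position p at which the remainder of the read matches a prefix of
// the adapter (length >= min_overlap, mismatch fraction <= max_mm_frac);
// returns the retained read length (p), or the full length when no match.
// Internal full-adapter occurrences are covered by the same scan.
// [[Rcpp::export]]
IntegerVector cpp_clip_positions(CharacterVector seqs, std::string adapter,
                                 int min_overlap, double max_mm_frac) {
  const int alen = (int)adapter.size();
  IntegerVector out(seqs.size());
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    std::string s = as<std::string>(seqs[r]);
    // iterate to fixpoint so the operation is idempotent: after a clip the
    // new suffix may itself match an adapter prefix
    int n = (int)s.size();
    for (;;) {
      int clip = n;
      for (int p = 0; p < n; ++p) {
        int L = std::min(n - p, alen);
        if (L < min_overlap) break; // L only shrinks as p grows
        int allowed = (int)std::floor(max_mm_frac * L + 1e-9);
        int mm = 0;
        bool ok = true;
        for (int i = 0; i < L; ++i) {
          if (s[p + i] != adapter[i] && ++mm > allowed) { ok = false; break; }
        }
        if (ok) { clip = p; break; }
      }
      if (clip == n) break;
      n = clip;
    }
    out[r] = n;
  }
  return out;
}

// retained length after removing 3'-terminal bases with quality < threshold
// (qualities are Phred+33 strings)
// [[Rcpp::export]]
IntegerVector cpp_qtrim_lengths(CharacterVector quals, int threshold) {
  IntegerVector out(quals.size());
  for (R_xlen_t r = 0; r < quals.size(); ++r) {
    std::string q = as<std::string>(quals[r]);
    int i = (int)q.size();
    while (i > 0 && ((int)q[i - 1] - 33) < threshold) --i;
    out[r] = i;
  }
  return out;
}

// Merge each forward read with the reverse complement of its mate. The best
// suffix(fwd)/prefix(revcomp(rev)) overlap with length >= min_overlap and
// mismatch fraction <= max_mm_frac is chosen by score = matches - mismatches;
// ties go to the longest overlap. Consensus at disagreeing positions takes
// the higher-quality base with quality max(2, |q1-q2|); agreements take the
// maximum quality.
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector fseq, CharacterVector fqual,
                     CharacterVector rseq, CharacterVector rqual,
                     int min_overlap, double max_mm_frac) {
  R_xlen_t n = fseq.size();
  CharacterVector mseq(n), mqual(n);
  LogicalVector merged(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string f = as<std::string>(fseq[i]);
    std::string fq = as<std::string>(fqual[i]);
    std::string r = revcomp(as<std::string>(rseq[i]));
    std::string rq = as<std::string>(rqual[i]);
    std::reverse(rq.begin(), rq.end());
    const int n1 = (int)f.size(), n2 = (int)r.size();
    const int maxL = std::min(n1, n2);

    int bestL = 0;
    long bestScore = LONG_MIN;
    for (int L = min_overlap; L <= maxL; ++L) {
      int allowed = (int)std::floor(max_mm_frac * L + 1e-9);
      int mm = 0;
      bool ok = true;
      for (int t = 0; t < L; ++t) {
        if (f[n1 - L + t] != r[t] && ++mm > allowed) { ok = false; break; }
      }
      if (!ok) continue;
      long score = (long)L - 2L * mm;
      if (score > bestScore || (score == bestScore && L > bestL)) {
        bestScore = score;
        bestL = L;
      }
    }

    if (bestL < 1) {
      merged[i] = false;
      mseq[i] = "";
      mqual[i] = "";
      continue;
    }
    std::string seq = f.substr(0, n1 - bestL);
    std::string qual = fq.substr(0, n1 - bestL);
    for (int t = 0; t < bestL; ++t) {
      char fb = f[n1 - bestL + t], rb = r[t];
      int q1 = (int)fq[n1 - bestL + t] - 33, q2 = (int)rq[t] - 33;
      if (fb == rb) {
        seq.push_back(fb);
        qual.push_back((char)(33 + std::max(q1, q2)));
      } else {
        char b = (q2 > q1) ? rb : fb; // tie -> forward base
        int q = std::max(2, std::abs(q1 - q2));
        seq.push_back(b);
        qual.push_back((char)(33 + q));
      }
    }
    seq += r.substr(bestL);
    qual += rq.substr(bestL);
    merged[i] = true;
    mseq[i] = seq;
    mqual[i] = qual;
  }
  return List::create(_["seq"] = mseq, _["qual"] = mqual, _["merged"] = merged);
}
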