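// library simulation inner loops: terminal deamination damage and paired-end
// sequencing with adapter read-through. All randomness comes from the R RNG,
// so results are a pure function of the R-side seed.

#include "common.h"

using namespace Rcpp;

// C->T at 5'-offset i with probability rate * decay^i, and symmetrically
// G->A from the 3' end (complementary-strand convention).
// [[Rcpp::export]]
CharacterVector cpp_apply_damage(CharacterVector seqs, double rate,
                                 double decay) {
  CharacterVector out(seqs.size());
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    std::string s = as<std::string>(seqs[r]);
    double p = rate;
    for (size_t i = 0; i < s.size() && p > 1e-12; ++i, p *= decay) {
      if (s[i] == 'C' && unif_rand() < p) s[i] = 'T';
    }
    p = rate;
    for (size_t i = 0; i < s.size() && p > 1e-12; ++i, p *= decay) {
      size_t j = s.size() - 1 - i;
      if (s[j] == 'G' && unif_rand() < p) s[j] = 'A';
    }
    out[r] = s;
  }
  return out;
}

namespace {

const char BASES[4] = {'A', 'C', 'G', 'T'};

int base_index(char b) {
  switch (b) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    default:  return 3;
  }
}

// sequence read_len bases from template (fragment + adapter), padding with
// 'A' at quality pad_q beyond the template; substitution errors at rate err.
void make_read(const std::string& tpl, int read_len, double err, int q_high,
               int q_low, bool couple, int pad_q, std::string& seq,
               std::string& qual) {
  seq.assign(read_len, 'A');
  qual.assign(read_len, (char)(33 + pad_q));
  int n_real = std::min((int)tpl.size(), read_len);
  for (int i = 0; i < n_real; ++i) {
    char b = tpl[i];
    bool e = (err > 0.0 && unif_rand() < err);
    if (e) {
      int j = (int)(unif_rand() * 3.0);
      if (j > 2) j = 2;
      int bi = base_index(b);
      // j-th base distinct from b
      int pick = (j >= bi) ? j + 1 : j;
      b = BASES[pick];
    }
    seq[i] = b;
    qual[i] = (char)(33 + ((couple && e) ? q_low : q_high));
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_sequence_reads(CharacterVector frags, std::string adapter,
                        int read_len, double err, int q_high, int q_low,
                        bool couple, int pad_q) {
  R_xlen_t n = frags.size();
  CharacterVector fs(n), fq(n), rs(n), rq(n);
  std::string seq, qual;
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string frag = as<std::string>(frags[i]);
    make_read(frag + adapter, read_len, err, q_high, q_low, couple, pad_q,
              seq, qual);
    fs[i] = seq;
    fq[i] = qual;
    make_read(revcomp(frag) + adapter, read_len, err, q_high, q_low, couple,
              pad_q, seq, qual);
    rs[i] = seq;
    rq[i] = qual;
  }
  return List::create(_["fwd_seq"] = fs, _["fwd_qual"] = fq,
                      _["rev_seq"] = rs, _["rev_qual"] = rq);
}
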