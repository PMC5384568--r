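// second layer primitives: maximal exact suffix-prefix overlaps between all
// oriented contig pairs (rolling-hash filtered, memcmp verified, so output is
// identical to the quadratic scan) and substring containment detection.

#include "common.h"

using namespace Rcpp;

namespace {

typedef unsigned long long u64;
const u64 HB = 1315423911ULL;

std::vector<u64>& pow_table(size_t need) {
  static std::vector<u64> P(1, 1ULL);
  while (P.size() <= need) P.push_back(P.back() * HB);
  return P;
}

struct PrefHash {
  std::string s;
  std::vector<u64> h; // h[i] = hash of s[0..i)
  void init(const std::string& str) {
    s = str;
    h.resize(s.size() + 1);
    h[0] = 0;
    for (size_t i = 0; i < s.size(); ++i)
      h[i + 1] = h[i] * HB + (unsigned char)s[i];
    pow_table(s.size());
  }
  u64 sub(size_t i, size_t j) const { // hash of s[i..j)
    return h[j] - h[i] * pow_table(0)[j - i];
  }
};

} // namespace

// All maximal exact suffix-prefix overlaps of length >= min_overlap between
// oriented contigs (from's 3' end onto to's 5' end). Containments are not
// reported (overlap length is capped at min(len)-1); self-overlaps are
// skipped. Orientation 0 = forward, 1 = reverse complement.
// [[Rcpp::export]]
DataFrame cpp_all_overlaps(CharacterVector seqs, int min_overlap) {
  const int n = seqs.size();
  std::vector<PrefHash> ph(2 * n); // [2*i] forward, [2*i+1] revcomp
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    ph[2 * i].init(s);
    ph[2 * i + 1].init(revcomp(s));
  }
  std::vector<int> from, to, len;
  std::vector<int> ofrom, oto;
  for (int q = 0; q < n; ++q) {
    for (int t = 0; t < n; ++t) {
      if (q == t) continue;
      for (int qo = 0; qo < 2; ++qo) {
        const PrefHash& A = ph[2 * q + qo];
        const size_t na = A.s.size();
        for (int to_ = 0; to_ < 2; ++to_) {
          const PrefHash& B = ph[2 * t + to_];
          const size_t nb = B.s.size();
          int lmax = (int)std::min(na, nb) - 1;
          for (int L = lmax; L >= min_overlap; --L) {
            if (A.sub(na - L, na) == B.sub(0, L) &&
                A.s.compare(na - L, L, B.s, 0, L) == 0) {
              from.push_back(q + 1);
              ofrom.push_back(qo);
              to.push_back(t + 1);
              oto.push_back(to_);
              len.push_back(L);
              break; // maximal overlap only
            }
          }
        }
      }
    }
  }
  return DataFrame::create(_["from"] = from, _["fromOrient"] = ofrom,
                           _["to"] = to, _["toOrient"] = oto,
                           _["length"] = len);
}

// ordered containment pairs: row (i, j) means seqs[j] occurs as a substring
// of seqs[i] in either orientation (i != j). `equal` flags equal lengths.
// [[Rcpp::export]]
DataFrame cpp_containments(CharacterVector seqs) {
  const int n = seqs.size();
  std::vector<std::string> S(n), RC(n);
  for (int i = 0; i < n; ++i) {
    S[i] = as<std::string>(seqs[i]);
    RC[i] = revcomp(S[i]);
  }
  std::vector<int> container, contained;
  std::vector<bool> equal;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i == j || S[j].size() > S[i].size()) continue;
      if (S[i].find(S[j]) != std::string::npos ||
          RC[i].find(S[j]) != std::string::npos) {
        container.push_back(i + 1);
        contained.push_back(j + 1);
        equal.push_back(S[i].size() == S[j].size());
      }
    }
  }
  return DataFrame::create(_["container"] = container,
                           _["contained"] = contained, _["equal"] = equal);
}
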