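#ifndef ADNA_COMMON_H
#define ADNA_COMMON_H

#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <unordered_set>

inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

inline std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (std::string::iterator it = r.begin(); it != r.end(); ++it)
    *it = comp_base(*it);
  return r;
}

inline bool is_acgt(const std::string& s) {
  for (size_t i = 0; i < s.size(); ++i) {
    char c = s[i];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T') return false;
  }
  return true;
}

// lexicographically smaller of a sequence and its reverse complement
inline std::string canonical(const std::string& s) {
  std::string r = revcomp(s);
  return s <= r ? s : r;
}

#endif
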