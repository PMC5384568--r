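// seed-and-extend aligners: read-vs-contig support testing (ungapped,
// presence/absence) and contig-vs-reference local mapping (per-diagonal
// X-drop extension, split alignments permitted).

#include "common.h"
#include <map>
#include <set>
#include <cmath>

using namespace Rcpp;

// A read supports a contig when some ungapped alignment (exact seed_len-mer
// seed, either strand) covers >= min_read_cover of the read at identity
// >= min_identity. Returns per-contig supporting-read counts and the best
// identity examined per contig.
// [[Rcpp::export]]
List cpp_read_support(CharacterVector reads, CharacterVector contigs,
                      int seed_len, double min_identity,
                      double min_read_cover) {
  const int nc = contigs.size();
  std::vector<std::string> C(nc);
  std::unordered_map<std::string, std::vector<std::pair<int, int> > > idx;
  for (int c = 0; c < nc; ++c) {
    C[c] = as<std::string>(contigs[c]);
    const std::string& s = C[c];
    if ((int)s.size() < seed_len) continue;
    for (size_t p = 0; p + seed_len <= s.size(); ++p) {
      std::string sd = s.substr(p, seed_len);
      if (is_acgt(sd)) idx[sd].push_back(std::make_pair(c, (int)p));
    }
  }

  IntegerVector count(nc);
  NumericVector best(nc);
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string rd = as<std::string>(reads[r]);
    const int n = (int)rd.size();
    if (n < seed_len) continue;
    std::set<int> supported;
    std::map<int, double> bestid;
    for (int o = 0; o < 2; ++o) {
      std::string s = o ? revcomp(rd) : rd;
      std::unordered_set<long long> tried;
      for (int p = 0; p + seed_len <= n; ++p) {
        std::unordered_map<std::string,
                           std::vector<std::pair<int, int> > >::iterator it =
            idx.find(s.substr(p, seed_len));
        if (it == idx.end()) continue;
        for (size_t h = 0; h < it->second.size(); ++h) {
          int c = it->second[h].first;
          if (supported.count(c)) continue;
          long long diag = (long long)it->second[h].second - p;
          long long key = ((long long)c * 4000037LL + diag) * 2LL + o;
          if (!tried.insert(key).second) continue;
          const std::string& cs = C[c];
          int qs = (int)std::max(0LL, -diag);
          int qe = (int)std::min((long long)n, (long long)cs.size() - diag);
          int span = qe - qs;
          if (span <= 0) continue;
          int match = 0;
          for (int q = qs; q < qe; ++q)
            if (s[q] == cs[q + diag]) ++match;
          double id = (double)match / span;
          std::map<int, double>::iterator b = bestid.find(c);
          if (b == bestid.end() || id > b->second) bestid[c] = id;
          if (span >= (int)std::ceil(min_read_cover * n - 1e-9) &&
              id >= min_identity - 1e-12)
            supported.insert(c);
        }
      }
    }
    for (std::set<int>::iterator s = supported.begin(); s != supported.end();
         ++s)
      count[*s] += 1;
    for (std::map<int, double>::iterator b = bestid.begin(); b != bestid.end();
         ++b)
      if (b->second > best[b->first]) best[b->first] = b->second;
  }
  return List::create(_["count"] = count, _["best_identity"] = best);
}

namespace {

struct Cand {
  int qs, qe;     // contig interval, original coordinates, 0-based half-open
  int rs, re;     // reference interval
  bool minus;
  double identity;
};

bool cand_order(const Cand& a, const Cand& b) {
  int la = a.qe - a.qs, lb = b.qe - b.qs;
  if (la != lb) return la > lb;
  if (a.identity != b.identity) return a.identity > b.identity;
  if (a.rs != b.rs) return a.rs < b.rs;
  if (a.minus != b.minus) return !a.minus;
  return a.qs < b.qs;
}

} // namespace

// Local alignments of each contig against a single reference sequence:
// exact seed_len-mer seeds grouped by diagonal, ungapped X-drop extension
// around the seed block, candidates >= min_identity selected greedily so the
// accepted alignments are non-overlapping on the contig.
// [[Rcpp::export]]
DataFrame cpp_map_contigs(CharacterVector contigs, std::string ref,
                          int seed_len, double min_identity) {
  const int R = (int)ref.size();
  std::unordered_map<std::string, std::vector<int> > idx;
  if (R >= seed_len)
    for (int p = 0; p + seed_len <= R; ++p) {
      std::string sd = ref.substr(p, seed_len);
      if (is_acgt(sd)) idx[sd].push_back(p);
    }

  std::vector<int> out_contig, out_rs, out_re, out_qs, out_qe;
  std::vector<std::string> out_strand;
  std::vector<double> out_id;

  for (R_xlen_t ci = 0; ci < contigs.size(); ++ci) {
    std::string fwd = as<std::string>(contigs[ci]);
    const int n = (int)fwd.size();
    std::vector<Cand> cands;
    for (int o = 0; o < 2; ++o) {
      std::string s = o ? revcomp(fwd) : fwd;
      if (n < seed_len) continue;
      std::map<long long, std::vector<int> > byDiag;
      for (int p = 0; p + seed_len <= n; ++p) {
        std::unordered_map<std::string, std::vector<int> >::iterator it =
            idx.find(s.substr(p, seed_len));
        if (it == idx.end()) continue;
        for (size_t h = 0; h < it->second.size(); ++h)
          byDiag[(long long)it->second[h] - p].push_back(p);
      }
      for (std::map<long long, std::vector<int> >::iterator d = byDiag.begin();
           d != byDiag.end(); ++d) {
        long long diag = d->first;
        std::vector<int>& qpos = d->second;
        int q0 = qpos.front();
        int q1 = qpos.back() + seed_len; // seed block, half-open
        int lo = (int)std::max(0LL, -diag);
        int hi = (int)std::min((long long)n, (long long)R - diag);
        // X-drop ungapped extension (match +1, mismatch -3, drop 12)
        int endq = q1, score = 0, bestscore = 0, bestend = q1;
        for (int q = q1; q < hi; ++q) {
          score += (s[q] == ref[q + diag]) ? 1 : -3;
          if (score > bestscore) { bestscore = score; bestend = q + 1; }
          if (score < bestscore - 12) break;
        }
        endq = bestend;
        int startq = q0;
        score = 0;
        bestscore = 0;
        int beststart = q0;
        for (int q = q0 - 1; q >= lo; --q) {
          score += (s[q] == ref[q + diag]) ? 1 : -3;
          if (score > bestscore) { bestscore = score; beststart = q; }
          if (score < bestscore - 12) break;
        }
        startq = beststart;
        int len = endq - startq;
        if (len < seed_len) continue;
        int match = 0;
        for (int q = startq; q < endq; ++q)
          if (s[q] == ref[q + diag]) ++match;
        double id = (double)match / len;
        if (id < min_identity - 1e-12) continue;
        Cand c;
        c.rs = (int)(startq + diag);
        c.re = (int)(endq + diag);
        c.minus = (o == 1);
        c.identity = id;
        if (o == 0) { c.qs = startq; c.qe = endq; }
        else        { c.qs = n - endq; c.qe = n - startq; }
        cands.push_back(c);
      }
    }
    std::sort(cands.begin(), cands.end(), cand_order);
    std::vector<std::pair<int, int> > accepted;
    for (size_t i = 0; i < cands.size(); ++i) {
      bool clash = false;
      for (size_t a = 0; a < accepted.size(); ++a) {
        if (cands[i].qs < accepted[a].second &&
            accepted[a].first < cands[i].qe) { clash = true; break; }
      }
      if (clash) continue;
      accepted.push_back(std::make_pair(cands[i].qs, cands[i].qe));
      out_contig.push_back((int)ci + 1);
      out_rs.push_back(cands[i].rs);
      out_re.push_back(cands[i].re);
      out_strand.push_back(cands[i].minus ? "-" : "+");
      out_id.push_back(cands[i].identity);
      out_qs.push_back(cands[i].qs);
      out_qe.push_back(cands[i].qe);
    }
  }
  return DataFrame::create(_["contig"] = out_contig, _["rstart"] = out_rs,
                           _["rend"] = out_re, _["strand"] = out_strand,
                           _["identity"] = out_id, _["qstart"] = out_qs,
                           _["qend"] = out_qe,
                           _["stringsAsFactors"] = false);
}
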