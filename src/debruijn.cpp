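// de Bruijn layer: canonical k-mer counting, graph cleaning (coverage filter,
// tip clipping, simple bubble popping) and unitig (maximal unbranched path)
// extraction. k-mers are stored in canonical form; traversal is bidirected.

#include "common.h"
#include <deque>
#include <map>

using namespace Rcpp;

namespace {

struct DBG {
  int k;
  std::unordered_map<std::string, int> cnt; // canonical k-mer -> multiplicity

  bool has(const std::string& s) const {
    return cnt.find(canonical(s)) != cnt.end();
  }

  // oriented successors / predecessors (overlap of k-1)
  std::vector<std::string> succ(const std::string& km) const {
    static const char B[4] = {'A', 'C', 'G', 'T'};
    std::vector<std::string> out;
    std::string t = km.substr(1) + "A";
    for (int i = 0; i < 4; ++i) {
      t[k - 1] = B[i];
      if (has(t)) out.push_back(t);
    }
    return out;
  }

  std::vector<std::string> pred(const std::string& km) const {
    static const char B[4] = {'A', 'C', 'G', 'T'};
    std::vector<std::string> out;
    std::string t = "A" + km.substr(0, k - 1);
    for (int i = 0; i < 4; ++i) {
      t[0] = B[i];
      if (has(t)) out.push_back(t);
    }
    return out;
  }
};

// maximal unbranched paths; every k-mer node lands in exactly one path.
// Seeds are visited in lexicographic order so the result is independent of
// input order.
std::vector<std::vector<std::string> > unitig_paths(const DBG& g) {
  std::vector<std::string> keys;
  keys.reserve(g.cnt.size());
  for (std::unordered_map<std::string, int>::const_iterator it = g.cnt.begin();
       it != g.cnt.end(); ++it)
    keys.push_back(it->first);
  std::sort(keys.begin(), keys.end());

  std::unordered_set<std::string> visited;
  std::vector<std::vector<std::string> > paths;

  for (size_t s = 0; s < keys.size(); ++s) {
    const std::string& seed = keys[s];
    if (visited.count(seed)) continue;
    std::deque<std::string> path;
    path.push_back(seed);
    visited.insert(seed);

    std::string cur = seed;
    for (;;) { // forward
      std::vector<std::string> nxt = g.succ(cur);
      if (nxt.size() != 1) break;
      const std::string& t = nxt[0];
      if (visited.count(canonical(t))) break;
      if (g.pred(t).size() != 1) break;
      path.push_back(t);
      visited.insert(canonical(t));
      cur = t;
    }
    cur = seed;
    for (;;) { // backward
      std::vector<std::string> prv = g.pred(cur);
      if (prv.size() != 1) break;
      const std::string& t = prv[0];
      if (visited.count(canonical(t))) break;
      if (g.succ(t).size() != 1) break;
      path.push_front(t);
      visited.insert(canonical(t));
      cur = t;
    }
    paths.push_back(std::vector<std::string>(path.begin(), path.end()));
  }
  return paths;
}

std::string spell(const std::vector<std::string>& path) {
  std::string s = path[0];
  for (size_t i = 1; i < path.size(); ++i) s.push_back(path[i][path[i].size() - 1]);
  return s;
}

List map_to_list(const DBG& g) {
  std::vector<std::string> keys;
  keys.reserve(g.cnt.size());
  for (std::unordered_map<std::string, int>::const_iterator it = g.cnt.begin();
       it != g.cnt.end(); ++it)
    keys.push_back(it->first);
  std::sort(keys.begin(), keys.end());
  CharacterVector km(keys.size());
  IntegerVector ct(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    km[i] = keys[i];
    ct[i] = g.cnt.find(keys[i])->second;
  }
  return List::create(_["kmers"] = km, _["counts"] = ct);
}

DBG list_to_map(CharacterVector kmers, IntegerVector counts, int k) {
  DBG g;
  g.k = k;
  for (R_xlen_t i = 0; i < kmers.size(); ++i)
    g.cnt[as<std::string>(kmers[i])] = counts[i];
  return g;
}

// remove every k-mer of a path from the graph
void erase_path(DBG& g, const std::vector<std::string>& path) {
  for (size_t i = 0; i < path.size(); ++i) g.cnt.erase(canonical(path[i]));
}

// iterative tip clipping: a tip is a path with exactly one dead end whose
// spelled length is below max_tip_bp
void clip_tips(DBG& g, int max_tip_bp) {
  for (;;) {
    std::vector<std::vector<std::string> > paths = unitig_paths(g);
    bool removed = false;
    for (size_t i = 0; i < paths.size(); ++i) {
      const std::vector<std::string>& p = paths[i];
      int bp = g.k + (int)p.size() - 1;
      if (bp >= max_tip_bp) continue;
      size_t df = g.pred(p.front()).size();
      size_t db = g.succ(p.back()).size();
      // the immediate path neighbours are counted too when |p| > 1, so look
      // at external degree: for interior-of-path ends nothing changes because
      // unitig ends have their path neighbour outside the front/back k-mer
      if ((df == 0) != (db == 0)) {
        erase_path(g, p);
        removed = true;
      }
    }
    if (!removed) break;
  }
}

// collapse simple two-path bubbles: parallel unitigs whose single flanking
// predecessor and successor k-mers coincide; the higher mean-coverage path
// survives (ties: lexicographically smaller spelling).
void pop_bubbles(DBG& g) {
  std::vector<std::vector<std::string> > paths = unitig_paths(g);
  std::map<std::string, std::vector<size_t> > groups;
  for (size_t i = 0; i < paths.size(); ++i) {
    std::vector<std::string> prv = g.pred(paths[i].front());
    std::vector<std::string> nxt = g.succ(paths[i].back());
    if (prv.size() != 1 || nxt.size() != 1) continue;
    std::string k1 = prv[0] + "|" + nxt[0];
    std::string k2 = revcomp(nxt[0]) + "|" + revcomp(prv[0]);
    groups[std::min(k1, k2)].push_back(i);
  }
  for (std::map<std::string, std::vector<size_t> >::iterator it = groups.begin();
       it != groups.end(); ++it) {
    std::vector<size_t>& mem = it->second;
    if (mem.size() < 2) continue;
    size_t keep = mem[0];
    double best_cov = -1.0;
    std::string best_spell;
    for (size_t j = 0; j < mem.size(); ++j) {
      const std::vector<std::string>& p = paths[mem[j]];
      double cov = 0.0;
      for (size_t q = 0; q < p.size(); ++q)
        cov += g.cnt.find(canonical(p[q]))->second;
      cov /= (double)p.size();
      std::string sp = canonical(spell(p));
      if (cov > best_cov || (cov == best_cov && sp < best_spell)) {
        best_cov = cov;
        best_spell = sp;
        keep = mem[j];
      }
    }
    for (size_t j = 0; j < mem.size(); ++j)
      if (mem[j] != keep) erase_path(g, paths[mem[j]]);
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector reads, int k) {
  std::unordered_map<std::string, int> cnt;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    if (reads[r] == NA_STRING) continue;
    std::string s = as<std::string>(reads[r]);
    if ((int)s.size() < k) continue;
    for (size_t i = 0; i + k <= s.size(); ++i) {
      std::string km = s.substr(i, k);
      if (!is_acgt(km)) continue;
      cnt[canonical(km)] += 1;
    }
  }
  DBG g;
  g.k = k;
  g.cnt.swap(cnt);
  return map_to_list(g);
}

// [[Rcpp::export]]
List cpp_clean_graph(CharacterVector kmers, IntegerVector counts, int k,
                     int min_cov, int max_tip_bp) {
  DBG g = list_to_map(kmers, counts, k);
  if (min_cov > 1) {
    std::vector<std::string> drop;
    for (std::unordered_map<std::string, int>::iterator it = g.cnt.begin();
         it != g.cnt.end(); ++it)
      if (it->second < min_cov) drop.push_back(it->first);
    for (size_t i = 0; i < drop.size(); ++i) g.cnt.erase(drop[i]);
  }
  clip_tips(g, max_tip_bp);
  pop_bubbles(g);
  clip_tips(g, max_tip_bp);
  return map_to_list(g);
}

// [[Rcpp::export]]
CharacterVector cpp_extract_contigs(CharacterVector kmers, IntegerVector counts,
                                    int k) {
  DBG g = list_to_map(kmers, counts, k);
  std::vector<std::vector<std::string> > paths = unitig_paths(g);
  std::vector<std::string> contigs;
  contigs.reserve(paths.size());
  for (size_t i = 0; i < paths.size(); ++i) {
    std::string s = spell(paths[i]);
    std::string r = revcomp(s);
    contigs.push_back(s <= r ? s : r);
  }
  std::sort(contigs.begin(), contigs.end());
  return wrap(contigs);
}
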