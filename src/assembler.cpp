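// Minimal De Bruijn unitig assembler for small, repeat-poor genomes:
// canonical k-mers in a hash table, dead-end (tip) trimming, maximal
// non-branching paths emitted as contigs in a deterministic order.
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int b2i(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  }
  return -1;
}

static inline uint64_t rc_kmer(uint64_t x, int k) {
  x = ~x;
  x = ((x >> 2) & 0x3333333333333333ULL) | ((x & 0x3333333333333333ULL) << 2);
  x = ((x >> 4) & 0x0F0F0F0F0F0F0F0FULL) | ((x & 0x0F0F0F0F0F0F0F0FULL) << 4);
  x = __builtin_bswap64(x);
  return x >> (64 - 2 * k);
}

static inline uint64_t canon(uint64_t x, int k) {
  uint64_t r = rc_kmer(x, k);
  return x < r ? x : r;
}

static std::string decode(uint64_t x, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = "ACGT"[x & 3ULL];
    x >>= 2;
  }
  return s;
}

static std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
    case 'A': c = 'T'; break;
    case 'T': c = 'A'; break;
    case 'C': c = 'G'; break;
    case 'G': c = 'C'; break;
    }
  }
  return r;
}

struct Graph {
  int k;
  uint64_t mask;
  std::unordered_set<uint64_t> S; // canonical k-mers

  bool has(uint64_t km) const { return S.count(canon(km, k)) > 0; }

  int out_count(uint64_t o, uint64_t *next) const {
    int n = 0;
    for (uint64_t b = 0; b < 4; ++b) {
      uint64_t nx = ((o << 2) | b) & mask;
      if (has(nx)) { *next = nx; ++n; }
    }
    return n;
  }
};

struct Unitig {
  std::string seq;
  uint64_t first_or; // orientation of first k-mer as it appears in seq
  uint64_t last_or;
  std::vector<uint64_t> kmers; // canonical
};

static std::string walk_right(const Graph &G, uint64_t start_or,
                              std::unordered_set<uint64_t> &visited,
                              std::vector<uint64_t> &collected,
                              uint64_t *end_or) {
  std::string ext;
  uint64_t cur = start_or;
  while (true) {
    uint64_t nxt = 0;
    if (G.out_count(cur, &nxt) != 1) break;
    uint64_t tmp;
    if (G.out_count(rc_kmer(nxt, G.k), &tmp) != 1) break; // in-degree of nxt
    uint64_t cn = canon(nxt, G.k);
    if (visited.count(cn)) break;
    visited.insert(cn);
    collected.push_back(cn);
    ext += "ACGT"[nxt & 3ULL];
    cur = nxt;
  }
  *end_or = cur;
  return ext;
}

static std::vector<Unitig> build_unitigs(const Graph &G) {
  std::vector<uint64_t> keys(G.S.begin(), G.S.end());
  std::sort(keys.begin(), keys.end());
  std::unordered_set<uint64_t> visited;
  std::vector<Unitig> out;
  for (uint64_t c : keys) {
    if (visited.count(c)) continue;
    visited.insert(c);
    Unitig u;
    u.kmers.push_back(c);
    uint64_t right_end, left_end;
    std::string rext = walk_right(G, c, visited, u.kmers, &right_end);
    std::vector<uint64_t> lk;
    std::string lext = walk_right(G, rc_kmer(c, G.k), visited, lk, &left_end);
    for (uint64_t x : lk) u.kmers.push_back(x);
    u.seq = revcomp_str(lext) + decode(c, G.k) + rext;
    u.first_or = rc_kmer(left_end, G.k);
    u.last_or = right_end;
    out.push_back(std::move(u));
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_assemble(CharacterVector reads, int k = 31,
                             int min_count = 1, int tip_rounds = 3,
                             double bubble_frac = 0) {
  if (k < 5 || k > 31 || (k % 2) == 0)
    stop("k must be odd and in [5, 31]");
  const uint64_t mask = (1ULL << (2 * k)) - 1;

  std::unordered_map<uint64_t, uint32_t> counts;
  for (int i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    if ((int)s.size() < k) continue;
    uint64_t km = 0;
    int run = 0;
    for (int j = 0; j < (int)s.size(); ++j) {
      int b = b2i(s[j]);
      if (b < 0) { run = 0; km = 0; continue; }
      km = ((km << 2) | (uint64_t)b) & mask;
      if (++run >= k) counts[canon(km, k)]++;
    }
  }

  Graph G;
  G.k = k;
  G.mask = mask;
  for (auto &kv : counts)
    if ((int)kv.second >= min_count) G.S.insert(kv.first);

  // graph cleaning: trim short dead-end tips, and (when bubble_frac > 0)
  // remove short low-coverage bubble arms (both ends attached, coverage
  // below bubble_frac of the median k-mer multiplicity) so that minor
  // within-strain variants collapse onto the majority path
  for (int round = 0; round < tip_rounds; ++round) {
    double med = 0;
    if (bubble_frac > 0 && !G.S.empty()) {
      std::vector<uint32_t> cv;
      cv.reserve(G.S.size());
      for (uint64_t x : G.S) cv.push_back(counts[x]);
      std::nth_element(cv.begin(), cv.begin() + cv.size() / 2, cv.end());
      med = (double)cv[cv.size() / 2];
    }
    std::vector<Unitig> us = build_unitigs(G);
    std::vector<uint64_t> to_remove;
    for (auto &u : us) {
      uint64_t tmp;
      int dr = G.out_count(u.last_or, &tmp);
      int dl = G.out_count(rc_kmer(u.first_or, G.k), &tmp);
      bool dead_r = (dr == 0), dead_l = (dl == 0);
      bool is_tip = ((int)u.seq.size() <= 2 * k) && (dead_r != dead_l);
      bool is_arm = false;
      if (!is_tip && bubble_frac > 0 && dr > 0 && dl > 0 &&
          (int)u.seq.size() <= 3 * k) {
        double cov = 0;
        for (uint64_t x : u.kmers) cov += counts[x];
        cov /= (double)u.kmers.size();
        is_arm = cov < bubble_frac * med;
      }
      if (is_tip || is_arm)
        for (uint64_t x : u.kmers) to_remove.push_back(x);
    }
    if (to_remove.empty()) break;
    for (uint64_t x : to_remove) G.S.erase(x);
  }

  std::vector<Unitig> us = build_unitigs(G);
  std::vector<std::string> contigs;
  contigs.reserve(us.size());
  for (auto &u : us) {
    std::string rc = revcomp_str(u.seq);
    contigs.push_back(u.seq < rc ? u.seq : rc); // canonical orientation
  }
  std::sort(contigs.begin(), contigs.end(),
            [](const std::string &a, const std::string &b) {
              if (a.size() != b.size()) return a.size() > b.size();
              return a < b;
            });
  return wrap(contigs);
}
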