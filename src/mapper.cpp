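// Exact k-mer seeded, gap-free mapping kernel shared by fragment ANI,
// marker detection and read cross-mapping. Divergence handled here is
// substitution-only, so all alignments live on a single diagonal:
// seeds are chained per (reference, diagonal) and scored either by
// projecting the whole query onto the reference at that diagonal
// ("global" mode, used for ANI fragments and marker hits) or by X-drop
// ungapped extension of the chain ("local" mode, used for reads).
#include <Rcpp.h>
#include <unordered_map>
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

static std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
    case 'A': c = 'T'; break;
    case 'T': c = 'A'; break;
    case 'C': c = 'G'; break;
    case 'G': c = 'C'; break;
    default: c = 'N';
    }
  }
  return r;
}

struct Seed {
  int ref;
  int diag; // rpos - qpos
  int qpos;
};

struct Cand {
  int ref;
  char strand;      // '+' or '-' (query orientation)
  int qs, qe;       // on the oriented query, 0-based half-open
  int rs, re;       // on the reference
  int matches;
  int nkmers;
};

// [[Rcpp::export]]
DataFrame cpp_map(CharacterVector queries, CharacterVector refs, int k = 16,
                  int max_occ = 200, int min_chain = 1, int max_gap = 150,
                  bool local = false, bool best_only = false, int xdrop = 12,
                  int mismatch_pen = 3) {
  const int nref = refs.size();
  std::vector<std::string> R(nref);
  for (int i = 0; i < nref; ++i) R[i] = as<std::string>(refs[i]);

  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  // index references
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t>>> idx;
  for (int r = 0; r < nref; ++r) {
    const std::string &s = R[r];
    if ((int)s.size() < k) continue;
    uint64_t km = 0;
    int run = 0;
    for (int i = 0; i < (int)s.size(); ++i) {
      int b = b2i(s[i]);
      if (b < 0) { run = 0; km = 0; continue; }
      km = ((km << 2) | (uint64_t)b) & mask;
      if (++run >= k) idx[km].push_back({(int32_t)r, (int32_t)(i - k + 1)});
    }
  }
  if (max_occ > 0) {
    for (auto &kv : idx)
      if ((int)kv.second.size() > max_occ) kv.second.clear();
  }

  std::vector<int> o_query, o_ref, o_qs, o_qe, o_rs, o_re, o_matches, o_nk;
  std::vector<std::string> o_strand;
  std::vector<double> o_ident, o_cov;

  const int eff_gap = local ? max_gap : INT_MAX;

  for (int qi = 0; qi < (int)queries.size(); ++qi) {
    std::string qfwd = as<std::string>(queries[qi]);
    const int L = (int)qfwd.size();
    std::vector<Cand> cands;

    for (int st = 0; st < 2; ++st) {
      std::string q = (st == 0) ? qfwd : revcomp_str(qfwd);
      if (L < k) break;
      // collect seeds
      std::vector<Seed> seeds;
      uint64_t km = 0;
      int run = 0;
      for (int i = 0; i < L; ++i) {
        int b = b2i(q[i]);
        if (b < 0) { run = 0; km = 0; continue; }
        km = ((km << 2) | (uint64_t)b) & mask;
        if (++run >= k) {
          auto it = idx.find(km);
          if (it != idx.end()) {
            int qpos = i - k + 1;
            for (auto &pr : it->second)
              seeds.push_back({pr.first, pr.second - qpos, qpos});
          }
        }
      }
      if (seeds.empty()) continue;
      std::sort(seeds.begin(), seeds.end(), [](const Seed &a, const Seed &b) {
        if (a.ref != b.ref) return a.ref < b.ref;
        if (a.diag != b.diag) return a.diag < b.diag;
        return a.qpos < b.qpos;
      });

      // chain seeds on identical (ref, diag); break on query gap in local mode
      size_t i0 = 0;
      while (i0 < seeds.size()) {
        size_t j = i0 + 1;
        while (j < seeds.size() && seeds[j].ref == seeds[i0].ref &&
               seeds[j].diag == seeds[i0].diag &&
               seeds[j].qpos - seeds[j - 1].qpos <= eff_gap)
          ++j;
        int nk = (int)(j - i0);
        if (nk >= min_chain) {
          int ref = seeds[i0].ref, d = seeds[i0].diag;
          const std::string &RS = R[ref];
          int qlo, qhi;
          if (!local) {
            // project the whole query onto the reference at this diagonal
            qlo = std::max(0, -d);
            qhi = std::min(L, (int)RS.size() - d);
          } else {
            // X-drop ungapped extension from the chained anchor
            int aq0 = seeds[i0].qpos, aq1 = seeds[j - 1].qpos + k;
            int best = 0, sc = 0, bi = aq0;
            for (int p = aq0 - 1; p >= 0 && p + d >= 0; --p) {
              sc += (q[p] == RS[p + d]) ? 1 : -mismatch_pen;
              if (sc > best) { best = sc; bi = p; }
              if (sc < best - xdrop) break;
            }
            qlo = bi;
            best = 0; sc = 0; bi = aq1;
            for (int p = aq1; p < L && p + d < (int)RS.size(); ++p) {
              sc += (q[p] == RS[p + d]) ? 1 : -mismatch_pen;
              if (sc > best) { best = sc; bi = p + 1; }
              if (sc < best - xdrop) break;
            }
            qhi = bi;
          }
          if (qhi > qlo) {
            int m = 0;
            for (int p = qlo; p < qhi; ++p)
              if (q[p] == RS[p + d]) ++m;
            Cand c;
            c.ref = ref;
            c.strand = (st == 0) ? '+' : '-';
            c.qs = qlo; c.qe = qhi;
            c.rs = qlo + d; c.re = qhi + d;
            c.matches = m;
            c.nkmers = nk;
            cands.push_back(c);
          }
        }
        i0 = j;
      }
    }

    if (cands.empty()) continue;

    // deterministic ranking: matches desc, then ref asc, strand '+' first,
    // then reference start
    std::sort(cands.begin(), cands.end(), [](const Cand &a, const Cand &b) {
      if (a.matches != b.matches) return a.matches > b.matches;
      if (a.ref != b.ref) return a.ref < b.ref;
      if (a.strand != b.strand) return a.strand == '+';
      return a.rs < b.rs;
    });

    size_t keep_n = cands.size();
    std::vector<Cand> kept;
    if (best_only) {
      kept.push_back(cands[0]);
    } else {
      // drop candidates largely overlapping an already-kept locus on the
      // same reference (duplicate chains of one locus)
      for (size_t i = 0; i < keep_n; ++i) {
        bool dup = false;
        for (auto &kc : kept) {
          if (kc.ref != cands[i].ref) continue;
          int ov = std::min(kc.re, cands[i].re) - std::max(kc.rs, cands[i].rs);
          int len = std::min(kc.re - kc.rs, cands[i].re - cands[i].rs);
          if (ov > 0 && len > 0 && (double)ov / len > 0.5) { dup = true; break; }
        }
        if (!dup) kept.push_back(cands[i]);
      }
    }

    for (auto &c : kept) {
      int qs = c.qs, qe = c.qe;
      if (c.strand == '-') { qs = L - c.qe; qe = L - c.qs; } // original orientation
      o_query.push_back(qi + 1);
      o_ref.push_back(c.ref + 1);
      o_strand.push_back(std::string(1, c.strand));
      o_qs.push_back(qs);
      o_qe.push_back(qe);
      o_rs.push_back(c.rs);
      o_re.push_back(c.re);
      o_matches.push_back(c.matches);
      o_nk.push_back(c.nkmers);
      o_ident.push_back(100.0 * c.matches / (double)(c.qe - c.qs));
      o_cov.push_back((double)(c.qe - c.qs) / (double)L);
    }
  }

  return DataFrame::create(
      _["query"] = o_query, _["ref"] = o_ref, _["strand"] = o_strand,
      _["q_start"] = o_qs, _["q_end"] = o_qe, _["r_start"] = o_rs,
      _["r_end"] = o_re, _["matches"] = o_matches, _["n_kmers"] = o_nk,
      _["identity"] = o_ident, _["coverage"] = o_cov,
      _["stringsAsFactors"] = false);
}
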