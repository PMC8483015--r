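// Minimal de Bruijn graph assembler for fosmid-scale, high-coverage read sets.
// Canonical k-mers (lexicographic min of k-mer and reverse complement) are
// 2-bit packed into 128-bit words, so k is limited to 15..63 (odd).
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

typedef unsigned __int128 u128;

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

struct U128Hash {
  size_t operator()(const u128 &x) const {
    uint64_t lo = (uint64_t)x, hi = (uint64_t)(x >> 64);
    uint64_t h = lo * 0x9E3779B97F4A7C15ULL;
    h ^= hi + 0x632BE59BD9B4E019ULL + (h << 6) + (h >> 2);
    h ^= h >> 29; h *= 0xBF58476D1CE4E5B9ULL; h ^= h >> 32;
    return (size_t)h;
  }
};

static inline u128 revcomp_kmer(u128 x, int k) {
  u128 r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (u128)(3u - (unsigned)(x & 3));
    x >>= 2;
  }
  return r;
}

static inline u128 canonical(u128 x, int k) {
  u128 r = revcomp_kmer(x, k);
  return x < r ? x : r;
}

static std::string decode_kmer(u128 x, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = BITS2BASE[(unsigned)(x & 3)];
    x >>= 2;
  }
  return s;
}

typedef std::unordered_map<u128, uint32_t, U128Hash> KmerMap;

struct Unitig {
  std::string seq;
  double cov;
  bool cycle;
  std::vector<u128> canon_kmers;
  std::vector<u128> first_last;  // oriented first and last k-mer
};

// successors of an oriented k-mer present in `solid`
static inline int successors(const KmerMap &solid, u128 x, int k, u128 mask,
                             u128 *out) {
  int n = 0;
  for (unsigned b = 0; b < 4; ++b) {
    u128 y = ((x << 2) | (u128)b) & mask;
    if (solid.count(canonical(y, k))) out[n++] = y;
  }
  return n;
}

static inline int predecessors(const KmerMap &solid, u128 x, int k, u128 mask,
                               u128 *out) {
  int n = 0;
  int shift = 2 * (k - 1);
  for (unsigned b = 0; b < 4; ++b) {
    u128 y = (x >> 2) | ((u128)b << shift);
    if (solid.count(canonical(y, k))) out[n++] = y;
  }
  return n;
}

static void build_unitigs(const KmerMap &solid, int k, u128 mask,
                          const std::vector<u128> &keys,
                          std::vector<Unitig> &out) {
  out.clear();
  std::unordered_set<u128, U128Hash> visited;
  visited.reserve(solid.size() * 2);
  u128 nb[4];

  for (size_t ki = 0; ki < keys.size(); ++ki) {
    u128 start = keys[ki];
    if (visited.count(start)) continue;
    visited.insert(start);

    std::vector<u128> oriented;
    oriented.push_back(start);
    bool cycle = false;

    // forward extension
    u128 cur = start;
    while (true) {
      int ns = successors(solid, cur, k, mask, nb);
      if (ns != 1) break;
      u128 nxt = nb[0];
      u128 pb[4];
      int np = predecessors(solid, nxt, k, mask, pb);
      if (np != 1) break;
      if (nxt == start) { cycle = true; break; }
      u128 cn = canonical(nxt, k);
      if (visited.count(cn)) break;
      visited.insert(cn);
      oriented.push_back(nxt);
      cur = nxt;
    }

    // backward extension (cycles already closed)
    if (!cycle) {
      std::vector<u128> back;
      cur = start;
      while (true) {
        u128 pb[4];
        int np = predecessors(solid, cur, k, mask, pb);
        if (np != 1) break;
        u128 prv = pb[0];
        int ns = successors(solid, prv, k, mask, nb);
        if (ns != 1) break;
        if (prv == start) break;  // would be a cycle, found forward already
        u128 cn = canonical(prv, k);
        if (visited.count(cn)) break;
        visited.insert(cn);
        back.push_back(prv);
        cur = prv;
      }
      if (!back.empty()) {
        std::reverse(back.begin(), back.end());
        back.insert(back.end(), oriented.begin(), oriented.end());
        oriented.swap(back);
      }
    }

    Unitig u;
    u.cycle = cycle;
    u.seq = decode_kmer(oriented[0], k);
    u.seq.reserve(k + oriented.size());
    for (size_t i = 1; i < oriented.size(); ++i)
      u.seq.push_back(BITS2BASE[(unsigned)(oriented[i] & 3)]);
    double tot = 0.0;
    u.canon_kmers.reserve(oriented.size());
    for (size_t i = 0; i < oriented.size(); ++i) {
      u128 cn = canonical(oriented[i], k);
      u.canon_kmers.push_back(cn);
      tot += solid.at(cn);
    }
    u.cov = tot / (double)oriented.size();
    u.first_last.push_back(oriented.front());
    u.first_last.push_back(oriented.back());
    out.push_back(u);
  }
}

//' @noRd
// [[Rcpp::export]]
List cpp_assemble(CharacterVector reads, int k, int min_count) {
  if (k < 15 || k > 63 || k % 2 == 0)
    stop("k must be odd and within [15, 63] for the built-in assembler");
  if (min_count < 1) stop("min_count must be >= 1");

  u128 mask = (((u128)1) << (2 * k)) - 1;

  KmerMap counts;
  counts.reserve(1 << 20);
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char *s = CHAR(STRING_ELT(reads, r));
    int len = (int)LENGTH(STRING_ELT(reads, r));
    u128 fw = 0, rc = 0;
    int run = 0;
    for (int i = 0; i < len; ++i) {
      int b = base2bits(s[i]);
      if (b < 0) { run = 0; fw = 0; rc = 0; continue; }
      fw = ((fw << 2) | (u128)b) & mask;
      rc = (rc >> 2) | ((u128)(3 - b) << (2 * (k - 1)));
      if (++run >= k) {
        u128 cn = fw < rc ? fw : rc;
        counts[cn]++;
      }
    }
  }

  KmerMap solid;
  solid.reserve(counts.size());
  for (KmerMap::const_iterator it = counts.begin(); it != counts.end(); ++it)
    if ((int)it->second >= min_count) solid.insert(*it);
  counts.clear();

  std::vector<Unitig> unitigs;
  if (!solid.empty()) {
    // deterministic traversal order
    std::vector<u128> keys;
    keys.reserve(solid.size());
    for (KmerMap::const_iterator it = solid.begin(); it != solid.end(); ++it)
      keys.push_back(it->first);
    std::sort(keys.begin(), keys.end());

    build_unitigs(solid, k, mask, keys, unitigs);

    // iterative removal of short dead-end tips (< 2k bp) hanging off branches
    for (int round = 0; round < 8; ++round) {
      bool removed = false;
      u128 nb[4], pb[4];
      for (size_t i = 0; i < unitigs.size(); ++i) {
        Unitig &u = unitigs[i];
        if (u.cycle || (int)u.seq.size() >= 2 * k) continue;
        int np = predecessors(solid, u.first_last[0], k, mask, pb);
        int ns = successors(solid, u.first_last[1], k, mask, nb);
        // internal neighbours of a 1-kmer unitig are none; np/ns count external
        bool dead_left = (np == 0), dead_right = (ns == 0);
        if (dead_left != dead_right) {  // tip: dead on exactly one side
          for (size_t j = 0; j < u.canon_kmers.size(); ++j)
            solid.erase(u.canon_kmers[j]);
          removed = true;
        }
      }
      if (!removed) break;
      keys.clear();
      for (KmerMap::const_iterator it = solid.begin(); it != solid.end(); ++it)
        keys.push_back(it->first);
      std::sort(keys.begin(), keys.end());
      build_unitigs(solid, k, mask, keys, unitigs);
    }
  }

  R_xlen_t n = (R_xlen_t)unitigs.size();
  CharacterVector seqs(n);
  NumericVector cov(n);
  LogicalVector cyc(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    seqs[i] = unitigs[i].seq;
    cov[i] = unitigs[i].cov;
    cyc[i] = unitigs[i].cycle;
  }
  return List::create(_["seq"] = seqs, _["mean_cov"] = cov,
                      _["is_cycle"] = cyc);
}
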