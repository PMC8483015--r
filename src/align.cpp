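// Affine-gap pairwise alignment with optional diagonal banding, plus exact
// k-mer seed matching. Gap of length g costs gap_open + g * gap_ext.
// Traceback is stored as one byte per in-band cell:
//   bits 0-1: arg-max state of H at the cell (0=M, 1=X, 2=Y, 3=alignment start)
//   bit 2: X reached by gap extension (else opened from H at (i-1, j))
//   bit 3: Y reached by gap extension (else opened from H at (i, j-1))
#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
#include <unordered_map>
#include <climits>
#include <algorithm>

using namespace Rcpp;

static const int NEG = INT_MIN / 4;

// [[Rcpp::export]]
List cpp_affine_align(std::string a, std::string b,
                      int match, int mismatch, int gap_open, int gap_ext,
                      std::string mode, int band_lo, int band_hi) {
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0) stop("cannot align an empty sequence");
  bool global = (mode == "global"), local = (mode == "local"),
       overlap = (mode == "overlap");
  if (!global && !local && !overlap) stop("unknown alignment mode");

  if (band_lo < -m) band_lo = -m;
  if (band_hi > n) band_hi = n;
  if (global) {  // band must contain (0,0) and (m,n)
    if (band_lo > 0) band_lo = 0;
    if (band_hi < 0) band_hi = 0;
    if (band_lo > n - m) band_lo = n - m;
    if (band_hi < n - m) band_hi = n - m;
  }
  if (overlap) {  // must contain column j = 0 and the row-m endpoints
    if (band_lo > -m) band_lo = -m;
    if (band_hi < 0) band_hi = 0;
  }
  if (band_lo > band_hi) stop("empty alignment band");
  const int W = band_hi - band_lo + 1;
  const double cells = (double)(m + 1) * (double)W;
  if (cells > 6e8) stop("alignment problem too large (%.0f banded cells)", cells);

  std::vector<uint8_t> tb((size_t)(m + 1) * W, 3);
  std::vector<int> H0(W, NEG), X0(W, NEG), Y0(W, NEG);
  std::vector<int> H1(W, NEG), X1(W, NEG), Y1(W, NEG);

  int best = NEG, best_i = -1, best_j = -1;

  // row i = 0
  for (int d = 0; d < W; ++d) {
    int j = band_lo + d;
    if (j < 0 || j > n) continue;
    size_t t = (size_t)d;
    if (j == 0 || local) {
      H0[d] = 0; tb[t] = 3;
    } else {  // global / overlap: leading gap in a (Y state)
      Y0[d] = -(gap_open + gap_ext * j);
      H0[d] = Y0[d];
      tb[t] = (uint8_t)(2 | (j > 1 ? 8 : 0));
    }
    if (local && H0[d] >= best) { best = H0[d]; best_i = 0; best_j = j; }
  }

  for (int i = 1; i <= m; ++i) {
    std::fill(H1.begin(), H1.end(), NEG);
    std::fill(X1.begin(), X1.end(), NEG);
    std::fill(Y1.begin(), Y1.end(), NEG);
    const int jlo = std::max(0, i + band_lo), jhi = std::min(n, i + band_hi);
    for (int j = jlo; j <= jhi; ++j) {
      const int d = j - i - band_lo;
      size_t t = (size_t)i * W + d;

      if (j == 0) {
        if (local || overlap) {
          H1[d] = 0; tb[t] = 3;
        } else {  // global first column: gap in b (X state)
          int Xv = -(gap_open + gap_ext * i);
          H1[d] = Xv; X1[d] = Xv;
          tb[t] = (uint8_t)(1 | (i > 1 ? 4 : 0));
        }
        continue;
      }

      // M: from (i-1, j-1) -> previous row, same d
      int Mv = NEG;
      if (H0[d] > NEG) {
        int s = (a[(size_t)i - 1] == b[(size_t)j - 1]) ? match : mismatch;
        Mv = H0[d] + s;
      }
      // X: from (i-1, j) -> previous row, d + 1
      int Xv = NEG; bool x_ext = false;
      if (d + 1 < W) {
        int open_v = (H0[d + 1] > NEG) ? H0[d + 1] - gap_open - gap_ext : NEG;
        int ext_v = (X0[d + 1] > NEG) ? X0[d + 1] - gap_ext : NEG;
        if (ext_v > open_v) { Xv = ext_v; x_ext = true; } else Xv = open_v;
      }
      // Y: from (i, j-1) -> same row, d - 1
      int Yv = NEG; bool y_ext = false;
      if (d - 1 >= 0) {
        int open_v = (H1[d - 1] > NEG) ? H1[d - 1] - gap_open - gap_ext : NEG;
        int ext_v = (Y1[d - 1] > NEG) ? Y1[d - 1] - gap_ext : NEG;
        if (ext_v > open_v) { Yv = ext_v; y_ext = true; } else Yv = open_v;
      }

      int Hv = Mv, st = 0;
      if (Xv > Hv) { Hv = Xv; st = 1; }
      if (Yv > Hv) { Hv = Yv; st = 2; }
      if (local && Hv < 0) { Hv = 0; st = 3; }
      if (Hv <= NEG / 2) { Hv = NEG; st = 3; }

      H1[d] = Hv; X1[d] = Xv; Y1[d] = Yv;
      uint8_t code = (uint8_t)st;
      if (x_ext) code |= 4;
      if (y_ext) code |= 8;
      tb[t] = code;

      if (local && Hv > best) { best = Hv; best_i = i; best_j = j; }
      if (overlap && i == m && Hv > best) { best = Hv; best_i = i; best_j = j; }
    }
    H0.swap(H1); X0.swap(X1); Y0.swap(Y1);
  }

  if (global) {
    best_i = m; best_j = n;
    best = H0[n - m - band_lo];
  }
  if (best_i < 0) stop("no alignment endpoint found (band too narrow)");

  // traceback; matched (query, target) positions collected in reverse order
  int i = best_i, j = best_j;
  const int q_end = i, t_end = j;
  int n_match = 0, n_cols = 0;
  std::vector<int> mq, mt;

  int state = tb[(size_t)i * W + (j - i - band_lo)] & 3;
  while ((i > 0 || j > 0) && state != 3) {
    uint8_t code = tb[(size_t)i * W + (j - i - band_lo)];
    if (state == 0) {  // M
      ++n_cols;
      if (a[(size_t)i - 1] == b[(size_t)j - 1]) {
        ++n_match;
        mq.push_back(i - 1);
        mt.push_back(j - 1);
      }
      --i; --j;
      state = (i == 0 && j == 0) ? 3 : (tb[(size_t)i * W + (j - i - band_lo)] & 3);
    } else if (state == 1) {  // X consumes a
      ++n_cols;
      bool ext = (code & 4) != 0;
      --i;
      state = ext ? 1
                  : ((i == 0 && j == 0)
                         ? 3
                         : (tb[(size_t)i * W + (j - i - band_lo)] & 3));
    } else {  // Y consumes b
      ++n_cols;
      bool ext = (code & 8) != 0;
      --j;
      state = ext ? 2
                  : ((i == 0 && j == 0)
                         ? 3
                         : (tb[(size_t)i * W + (j - i - band_lo)] & 3));
    }
  }
  const int q_start = i, t_start = j;

  // run-length encode matched target positions into half-open intervals;
  // positions are strictly decreasing and co-linear on both sequences
  std::vector<int> ts, te, qs, qe;
  for (int idx = (int)mt.size() - 1; idx >= 0;) {
    int lo = idx;
    while (lo - 1 >= 0 && mt[(size_t)lo - 1] == mt[(size_t)lo] + 1 &&
           mq[(size_t)lo - 1] == mq[(size_t)lo] + 1)
      --lo;
    ts.push_back(mt[(size_t)idx]); te.push_back(mt[(size_t)lo] + 1);
    qs.push_back(mq[(size_t)idx]); qe.push_back(mq[(size_t)lo] + 1);
    idx = lo - 1;
  }

  return List::create(
      _["score"] = best, _["n_match"] = n_match, _["n_cols"] = n_cols,
      _["q_start"] = q_start, _["q_end"] = q_end,
      _["t_start"] = t_start, _["t_end"] = t_end,
      _["t_match_start"] = IntegerVector(ts.begin(), ts.end()),
      _["t_match_end"] = IntegerVector(te.begin(), te.end()),
      _["q_match_start"] = IntegerVector(qs.begin(), qs.end()),
      _["q_match_end"] = IntegerVector(qe.begin(), qe.end()));
}

// Exact k-mer seed hits of query against target (forward strands only; the
// caller handles reverse complements). k <= 31. Target k-mers occurring more
// than max_occ times are skipped as repeats.
// [[Rcpp::export]]
List cpp_seed_hits(std::string query, std::string target, int k, int max_occ) {
  if (k < 8 || k > 31) stop("seed k must be in [8, 31]");
  const int qn = (int)query.size(), tn = (int)target.size();
  std::vector<int> qpos, tpos;
  if (qn < k || tn < k)
    return List::create(_["qpos"] = IntegerVector(0),
                        _["tpos"] = IntegerVector(0));

  const uint64_t mask = (1ULL << (2 * k)) - 1;
  std::unordered_map<uint64_t, std::vector<int> > index;
  index.reserve((size_t)tn * 2);
  {
    uint64_t fw = 0; int run = 0;
    for (int i = 0; i < tn; ++i) {
      int b;
      switch (target[(size_t)i]) {
        case 'A': case 'a': b = 0; break;
        case 'C': case 'c': b = 1; break;
        case 'G': case 'g': b = 2; break;
        case 'T': case 't': b = 3; break;
        default: b = -1;
      }
      if (b < 0) { run = 0; fw = 0; continue; }
      fw = ((fw << 2) | (uint64_t)b) & mask;
      if (++run >= k) index[fw].push_back(i - k + 1);
    }
  }
  {
    uint64_t fw = 0; int run = 0;
    for (int i = 0; i < qn; ++i) {
      int b;
      switch (query[(size_t)i]) {
        case 'A': case 'a': b = 0; break;
        case 'C': case 'c': b = 1; break;
        case 'G': case 'g': b = 2; break;
        case 'T': case 't': b = 3; break;
        default: b = -1;
      }
      if (b < 0) { run = 0; fw = 0; continue; }
      fw = ((fw << 2) | (uint64_t)b) & mask;
      if (++run >= k) {
        std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
            index.find(fw);
        if (it != index.end() && (int)it->second.size() <= max_occ) {
          for (size_t h = 0; h < it->second.size(); ++h) {
            qpos.push_back(i - k + 1);
            tpos.push_back(it->second[h]);
            if (qpos.size() > 5000000)
              stop("too many seed hits; sequences look repetitive");
          }
        }
      }
    }
  }
  return List::create(_["qpos"] = IntegerVector(qpos.begin(), qpos.end()),
                      _["tpos"] = IntegerVector(tpos.begin(), tpos.end()));
}
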