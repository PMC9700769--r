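#include <Rcpp.h>
#include <vector>
#include <cstdlib>
using namespace Rcpp;

// 8-neighbourhood offsets; bit k of a configuration refers to this order.
static const int DR[8] = {-1, -1, -1,  0, 0,  1, 1, 1};
static const int DC[8] = {-1,  0,  1, -1, 1, -1, 0, 1};

// Connected-component labelling of a logical raster.
// eight = TRUE: 8-connectivity (foreground convention);
// eight = FALSE: 4-connectivity (background convention).
// Labels are 1..n in first-touch order of a column-major scan; 0 = not in set.
// [[Rcpp::export]]
IntegerMatrix cpp_label(const LogicalMatrix& mask, bool eight) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> qr, qc;
  qr.reserve(256); qc.reserve(256);
  int next = 0;
  for (int c0 = 0; c0 < W; ++c0) {
    for (int r0 = 0; r0 < H; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0)) continue;
      ++next;
      lab(r0, c0) = next;
      qr.clear(); qc.clear();
      qr.push_back(r0); qc.push_back(c0);
      for (size_t h = 0; h < qr.size(); ++h) {
        const int r = qr[h], c = qc[h];
        for (int k = 0; k < 8; ++k) {
          if (!eight && DR[k] != 0 && DC[k] != 0) continue;
          const int rr = r + DR[k], cc = c + DC[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) && !lab(rr, cc)) {
            lab(rr, cc) = next;
            qr.push_back(rr); qc.push_back(cc);
          }
        }
      }
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}

// Count connected components among the 8 ring cells of a 3x3 neighbourhood
// (centre excluded). cfg bit k set = cell k is foreground. When fg, count
// foreground cells under 8-connectivity; otherwise count background cells
// under 4-connectivity, restricted to components containing at least one
// 4-neighbour of the centre (cells with |dr|+|dc| == 1).
static int ring_components(int cfg, bool fg, bool eight, bool must_touch4) {
  bool in[8], seen[8];
  for (int k = 0; k < 8; ++k) {
    const bool f = (cfg >> k) & 1;
    in[k] = fg ? f : !f;
    seen[k] = false;
  }
  int comps = 0;
  std::vector<int> st;
  for (int s = 0; s < 8; ++s) {
    if (!in[s] || seen[s]) continue;
    bool touch = (std::abs(DR[s]) + std::abs(DC[s])) == 1;
    st.clear(); st.push_back(s); seen[s] = true;
    while (!st.empty()) {
      const int a = st.back(); st.pop_back();
      for (int b = 0; b < 8; ++b) {
        if (!in[b] || seen[b]) continue;
        const int dr = std::abs(DR[a] - DR[b]), dc = std::abs(DC[a] - DC[b]);
        const bool adj = eight ? (std::max(dr, dc) == 1)
                               : (dr + dc == 1);
        if (adj) {
          seen[b] = true;
          st.push_back(b);
          if (std::abs(DR[b]) + std::abs(DC[b]) == 1) touch = true;
        }
      }
    }
    if (!must_touch4 || touch) ++comps;
  }
  return comps;
}

// Simple-point lookup table over the 256 neighbourhood configurations.
// A pixel is simple iff deleting it changes neither the 8-connected
// foreground components nor the 4-connected background components of its
// 3x3 neighbourhood: exactly one foreground component, and exactly one
// background component 4-adjacent to the centre.
static bool SIMPLE[256];
static bool LUT_READY = false;

static void build_lut() {
  for (int cfg = 0; cfg < 256; ++cfg) {
    SIMPLE[cfg] = ring_components(cfg, true,  true,  false) == 1 &&
                  ring_components(cfg, false, false, true)  == 1;
  }
  LUT_READY = true;
}

static inline int cfg_at(const LogicalMatrix& m, int r, int c) {
  const int H = m.nrow(), W = m.ncol();
  int cfg = 0;
  for (int k = 0; k < 8; ++k) {
    const int rr = r + DR[k], cc = c + DC[k];
    if (rr >= 0 && rr < H && cc >= 0 && cc < W && m(rr, cc)) cfg |= (1 << k);
  }
  return cfg;
}

static inline int popcount8(int x) {
  int n = 0;
  while (x) { n += x & 1; x >>= 1; }
  return n;
}

// Topology-preserving thinning: repeated boundary erosion in which a pixel
// is removed only while its removal cannot disconnect the network or open
// a loop (simple-point test), stopping when no pixel is removable. Two
// directional sub-passes per pass (N/W borders then S/E borders) in raster
// order, fully sequential, so the result is deterministic. Pixels with a
// single foreground neighbour (arc endpoints) are retained so open cords
// keep their length.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(const LogicalMatrix& mask) {
  if (!LUT_READY) build_lut();
  LogicalMatrix m = clone(mask);
  const int H = m.nrow(), W = m.ncol();
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      for (int r = 0; r < H; ++r) {
        for (int c = 0; c < W; ++c) {
          if (!m(r, c)) continue;
          const bool nbg = (r == 0)     || !m(r - 1, c);
          const bool wbg = (c == 0)     || !m(r, c - 1);
          const bool sbg = (r == H - 1) || !m(r + 1, c);
          const bool ebg = (c == W - 1) || !m(r, c + 1);
          if (sub == 0 ? !(nbg || wbg) : !(sbg || ebg)) continue;
          const int cfg = cfg_at(m, r, c);
          if (popcount8(cfg) < 2) continue;  // keep endpoints and isolated px
          if (SIMPLE[cfg]) {
            m(r, c) = false;
            changed = true;
          }
        }
      }
    }
  }
  return m;
}

// Expose the simple-point test for unit testing of the lookup table.
// [[Rcpp::export]]
LogicalVector cpp_simple_lut() {
  if (!LUT_READY) build_lut();
  LogicalVector out(256);
  for (int i = 0; i < 256; ++i) out[i] = SIMPLE[i];
  return out;
}
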