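#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher).
// f: input squared distances, d: output, step: physical sample spacing.
static void edt1d(const std::vector<double>& f, std::vector<double>& d,
                  double step) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  // envelope over finite parabolas only; +Inf sources never contribute
  std::vector<int> idx;
  idx.reserve(n);
  for (int i = 0; i < n; ++i) if (R_finite(f[i])) idx.push_back(i);
  if (idx.empty()) { for (int i = 0; i < n; ++i) d[i] = INF; return; }
  const double s2 = step * step;
  std::vector<int> v(idx.size());
  std::vector<double> z(idx.size() + 1);
  int k = 0;
  v[0] = idx[0];
  z[0] = -INF;
  z[1] = INF;
  for (size_t m = 1; m < idx.size(); ++m) {
    int q = idx[m];
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (k > 0 && s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = s2 * (q - p) * (q - p) + f[p];
  }
}

// Squared Euclidean distance from every voxel to the nearest background
// (FALSE) voxel, with anisotropic spacing. Column-major 3D array.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const double INF = std::numeric_limits<double>::infinity();
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? INF : 0.0;

  std::vector<double> f, d;
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      edt1d(f, d, spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)y * nx];
      edt1d(f, d, spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = d[y];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = out[base + (R_xlen_t)z * nx * ny];
      edt1d(f, d, spacing[2]);
      for (int z = 0; z < nz; ++z) out[base + (R_xlen_t)z * nx * ny] = d[z];
    }
  return out;
}

// Connected-component labeling, connectivity 6 or 26.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> offs_dx, offs_dy, offs_dz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        offs_dx.push_back(dx); offs_dy.push_back(dy); offs_dz.push_back(dz);
      }
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int x = (int)(cur % nx);
      int y = (int)((cur / nx) % ny);
      int z = (int)(cur / ((R_xlen_t)nx * ny));
      for (size_t k = 0; k < offs_dx.size(); ++k) {
        int xx = x + offs_dx[k], yy = y + offs_dy[k], zz = z + offs_dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t q = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  return lab;
}

// --- simple-point machinery (Bertrand's 26/6 topological numbers) ---

static inline int nb_index(int dx, int dy, int dz) {
  return (dz + 1) * 9 + (dy + 1) * 3 + (dx + 1); // 0..26, 13 = center
}

// number of 26-connected components of foreground among the 26 neighbors
static int fg_components26(const bool nb[27]) {
  bool seen[27] = {false};
  int comps = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    ++comps;
    std::vector<int> st(1, i);
    seen[i] = true;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int xx = cx + dx, yy = cy + dy, zz = cz + dz;
            if (xx < 0 || xx > 2 || yy < 0 || yy > 2 || zz < 0 || zz > 2)
              continue;
            int q = zz * 9 + yy * 3 + xx;
            if (q == 13 || q == c || seen[q] || !nb[q]) continue;
            seen[q] = true;
            st.push_back(q);
          }
    }
  }
  return comps;
}

// number of 6-connected background components in the 18-neighborhood that
// are 6-adjacent to the center
static int bg_components6(const bool nb[27]) {
  // positions in the 18-neighborhood: manhattan distance 1 or 2 (not corners)
  auto in18 = [](int i) {
    int cx = i % 3 - 1, cy = (i / 3) % 3 - 1, cz = i / 9 - 1;
    int m = std::abs(cx) + std::abs(cy) + std::abs(cz);
    return m == 1 || m == 2;
  };
  bool seen[27] = {false};
  int comps = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || nb[i] || !in18(i) || seen[i]) continue;
    int cx = i % 3 - 1, cy = (i / 3) % 3 - 1, cz = i / 9 - 1;
    if (std::abs(cx) + std::abs(cy) + std::abs(cz) != 1) continue; // seed at face nbrs
    ++comps;
    std::vector<int> st(1, i);
    seen[i] = true;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int x = c % 3, y = (c / 3) % 3, z = c / 9;
      const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int xx = x + d6[k][0], yy = y + d6[k][1], zz = z + d6[k][2];
        if (xx < 0 || xx > 2 || yy < 0 || yy > 2 || zz < 0 || zz > 2) continue;
        int q = zz * 9 + yy * 3 + xx;
        if (q == 13 || seen[q] || nb[q] || !in18(q)) continue;
        seen[q] = true;
        st.push_back(q);
      }
    }
  }
  return comps;
}

struct ThinCtx {
  const int nx, ny, nz;
  std::vector<char> fg;
  ThinCtx(int nx_, int ny_, int nz_) : nx(nx_), ny(ny_), nz(nz_),
    fg((size_t)nx_ * ny_ * nz_, 0) {}
  inline bool at(int x, int y, int z) const {
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return false;
    return fg[(size_t)z * nx * ny + (size_t)y * nx + x] != 0;
  }
  void neighborhood(int x, int y, int z, bool nb[27]) const {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          nb[nb_index(dx, dy, dz)] = at(x + dx, y + dy, z + dz);
  }
  int n26(int x, int y, int z) const {
    bool nb[27]; neighborhood(x, y, z, nb);
    int c = 0;
    for (int i = 0; i < 27; ++i) if (i != 13 && nb[i]) ++c;
    return c;
  }
  bool simple(int x, int y, int z) const {
    bool nb[27]; neighborhood(x, y, z, nb);
    return fg_components26(nb) == 1 && bg_components6(nb) == 1;
  }
};

// Distance-ordered homotopic thinning to a curve skeleton. Voxels are
// processed in increasing `priority` (distance-to-surface) levels; at
// each level, six directional sub-iterations peel one layer at a time
// from opposite sides symmetrically, removing only simple points that
// are not curve endpoints. The directional sweeps prevent the one-sided
// erosion that otherwise leaves off-axis medial sheets and combs.
// [[Rcpp::export]]
LogicalVector cpp_thin(LogicalVector mask, IntegerVector dim,
                       NumericVector priority) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  ThinCtx ctx(nx, ny, nz);
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<R_xlen_t> fg_idx;
  for (R_xlen_t i = 0; i < n; ++i) {
    ctx.fg[i] = mask[i] ? 1 : 0;
    if (mask[i]) fg_idx.push_back(i);
  }
  if (fg_idx.empty()) return LogicalVector(n);
  // ascending unique priority levels
  std::vector<double> levels;
  for (size_t k = 0; k < fg_idx.size(); ++k)
    levels.push_back(priority[fg_idx[k]]);
  std::sort(levels.begin(), levels.end());
  levels.erase(std::unique(levels.begin(), levels.end()), levels.end());

  const int d6[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  std::vector<R_xlen_t> cand;
  for (size_t lv = 0; lv < levels.size(); ++lv) {
    double level = levels[lv];
    bool any = true;
    while (any) {
      any = false;
      for (int dir = 0; dir < 6; ++dir) {
        cand.clear();
        for (size_t k = 0; k < fg_idx.size(); ++k) {
          R_xlen_t i = fg_idx[k];
          if (!ctx.fg[(size_t)i] || priority[i] > level) continue;
          int x = (int)(i % nx);
          int y = (int)((i / nx) % ny);
          int z = (int)(i / ((R_xlen_t)nx * ny));
          int xx = x + d6[dir][0], yy = y + d6[dir][1],
              zz = z + d6[dir][2];
          if (ctx.at(xx, yy, zz)) continue;   // needs bg in this direction
          if (ctx.n26(x, y, z) <= 1) continue;
          if (!ctx.simple(x, y, z)) continue;
          cand.push_back(i);
        }
        for (size_t k = 0; k < cand.size(); ++k) {
          R_xlen_t i = cand[k];
          int x = (int)(i % nx);
          int y = (int)((i / nx) % ny);
          int z = (int)(i / ((R_xlen_t)nx * ny));
          if (ctx.n26(x, y, z) <= 1) continue;
          if (!ctx.simple(x, y, z)) continue;
          ctx.fg[(size_t)i] = 0;
          any = true;
        }
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = ctx.fg[(size_t)i] != 0;
  return out;
}
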