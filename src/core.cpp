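// Voxel-level primitives for 3D network reconstruction: connected-component
// labeling, topology-preserving thinning, Euclidean distance transform,
// separable Gaussian convolution, curvature-driven diffusion, sphere
// rasterization and skeleton chain extraction. All arrays are column-major
// (R layout), dims = (nx, ny, nz), linear index = x + nx*(y + ny*z).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
#include <algorithm>
#include <limits>
using namespace Rcpp;

static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 int n, double s);

// ---------------------------------------------------------------------------
// Connected-component labeling (6 or 26 connectivity), iterative flood fill.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);

  // neighbour offsets
  std::vector<int> ox, oy, oz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && man != 1) continue;
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
      }
  const int noff = (int)ox.size();

  int cur = 0;
  std::vector<int> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    lab[s] = cur;
    stack.clear();
    stack.push_back((int)s);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int z = v / (nx * ny), r = v % (nx * ny), y = r / nx, x = r % nx;
      for (int k = 0; k < noff; ++k) {
        int xx = x + ox[k], yy = y + oy[k], zz = z + oz[k];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        int w = lin(xx, yy, zz, nx, ny);
        if (mask[w] && lab[w] == 0) { lab[w] = cur; stack.push_back(w); }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Topology-preserving 3D curve thinning.
//
// Sequential border peeling over the 6 face directions; a voxel is deleted
// only if it is a simple point (deletion preserves local topology, tested by
// the two-component characterization: exactly one 26-connected foreground
// component in N26* and exactly one 6-connected background component in N18
// touching a face neighbour) and not a curve endpoint (>= 2 foreground
// neighbours). Iterates to a fixpoint, leaving one-voxel-wide centrelines.
// ---------------------------------------------------------------------------

namespace thinning {

// 27-cell neighbourhood tables, built once.
struct Tables {
  int pos[27][3];
  // adjacency among the 26 non-centre cells under 26-connectivity
  std::vector<int> adj26[27];
  // adjacency among the 18 face+edge cells under 6-connectivity
  std::vector<int> adj6[27];
  bool is18[27];
  bool isface[27];
  Tables() {
    int i = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx, ++i) {
          pos[i][0] = dx; pos[i][1] = dy; pos[i][2] = dz;
          int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
          is18[i] = (man == 1 || man == 2);
          isface[i] = (man == 1);
        }
    for (int a = 0; a < 27; ++a) {
      if (a == 13) continue;
      for (int b = 0; b < 27; ++b) {
        if (b == 13 || b == a) continue;
        int dx = std::abs(pos[a][0] - pos[b][0]);
        int dy = std::abs(pos[a][1] - pos[b][1]);
        int dz = std::abs(pos[a][2] - pos[b][2]);
        int cheb = std::max(dx, std::max(dy, dz));
        int man = dx + dy + dz;
        if (cheb == 1) adj26[a].push_back(b);
        if (man == 1 && is18[a] && is18[b]) adj6[a].push_back(b);
      }
    }
  }
};

static const Tables TAB;

// nb: foreground flags of the full 3x3x3 neighbourhood (centre included at 13)
static inline bool is_simple(const bool nb[27]) {
  // C*: 26-components of foreground in N26*
  bool seen[27] = {false};
  int ncomp_fg = 0;
  int stack[27], top;
  for (int a = 0; a < 27; ++a) {
    if (a == 13 || !nb[a] || seen[a]) continue;
    ++ncomp_fg;
    if (ncomp_fg > 1) return false;
    top = 0; stack[top++] = a; seen[a] = true;
    while (top) {
      int v = stack[--top];
      for (size_t k = 0; k < TAB.adj26[v].size(); ++k) {
        int w = TAB.adj26[v][k];
        if (nb[w] && !seen[w]) { seen[w] = true; stack[top++] = w; }
      }
    }
  }
  if (ncomp_fg != 1) return false;

  // C-bar: 6-components of background within N18 containing a face neighbour
  bool seenb[27] = {false};
  int ncomp_bg = 0;
  for (int a = 0; a < 27; ++a) {
    if (a == 13 || !TAB.isface[a] || nb[a] || seenb[a]) continue;
    ++ncomp_bg;
    if (ncomp_bg > 1) return false;
    top = 0; stack[top++] = a; seenb[a] = true;
    while (top) {
      int v = stack[--top];
      for (size_t k = 0; k < TAB.adj6[v].size(); ++k) {
        int w = TAB.adj6[v][k];
        if (!nb[w] && !seenb[w]) { seenb[w] = true; stack[top++] = w; }
      }
    }
  }
  return ncomp_bg == 1;
}

} // namespace thinning

// [[Rcpp::export]]
bool cpp_is_simple_probe(LogicalVector nb27) {
  bool nb[27];
  for (int i = 0; i < 27; ++i) nb[i] = nb27[i];
  return thinning::is_simple(nb);
}

// Distance-ordered homotopic thinning: simple points are deleted in
// increasing Euclidean-distance order (surface first), which keeps the
// surviving curve on the medial axis; curve endpoints (< 2 foreground
// neighbours) are never deleted. Iterates passes to a fixpoint.

// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<unsigned char> fg(n);
  for (R_xlen_t i = 0; i < n; ++i) fg[i] = mask[i] ? 1 : 0;

  // squared EDT to background (unit spacing; the grid is isotropic here)
  std::vector<double> g(n);
  {
    const double INF = 1e30;
    for (R_xlen_t i = 0; i < n; ++i) g[i] = fg[i] ? INF : 0.0;
    std::vector<double> f, d;
    f.resize(nx); d.resize(nx);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) f[x] = g[lin(x, y, z, nx, ny)];
        dt1d(f, d, nx, 1.0);
        for (int x = 0; x < nx; ++x) g[lin(x, y, z, nx, ny)] = d[x];
      }
    f.resize(ny); d.resize(ny);
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        for (int y = 0; y < ny; ++y) f[y] = g[lin(x, y, z, nx, ny)];
        dt1d(f, d, ny, 1.0);
        for (int y = 0; y < ny; ++y) g[lin(x, y, z, nx, ny)] = d[y];
      }
    f.resize(nz); d.resize(nz);
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        for (int z = 0; z < nz; ++z) f[z] = g[lin(x, y, z, nx, ny)];
        dt1d(f, d, nz, 1.0);
        for (int z = 0; z < nz; ++z) g[lin(x, y, z, nx, ny)] = d[z];
      }
  }

  auto fill_nb = [&](int x, int y, int z, bool nb[27], int &cnt) {
    cnt = 0;
    int i = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx, ++i) {
          int xx = x + dx, yy = y + dy, zz = z + dz;
          bool v = false;
          if (xx >= 0 && yy >= 0 && zz >= 0 && xx < nx && yy < ny && zz < nz)
            v = fg[lin(xx, yy, zz, nx, ny)] != 0;
          nb[i] = v;
          if (v && i != 13) ++cnt;
        }
  };

  std::vector<std::pair<double, int> > cand;
  bool changed = true;
  while (changed) {
    changed = false;
    cand.clear();
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int v = lin(x, y, z, nx, ny);
          if (!fg[v]) continue;
          // border voxel: some 6-neighbour is background
          bool border = false;
          if (x == 0 || !fg[v - 1]) border = true;
          else if (x == nx - 1 || !fg[v + 1]) border = true;
          else if (y == 0 || !fg[v - nx]) border = true;
          else if (y == ny - 1 || !fg[v + nx]) border = true;
          else if (z == 0 || !fg[v - nx * ny]) border = true;
          else if (z == nz - 1 || !fg[v + nx * ny]) border = true;
          if (border) cand.push_back(std::make_pair(g[v], v));
        }
    std::sort(cand.begin(), cand.end());
    for (size_t c = 0; c < cand.size(); ++c) {
      int v = cand[c].second;
      if (!fg[v]) continue;
      int z = v / (nx * ny), r = v % (nx * ny), y = r / nx, x = r % nx;
      bool nb[27]; int cnt;
      fill_nb(x, y, z, nb, cnt);
      if (cnt < 2) continue;               // keep curve endpoints
      if (thinning::is_simple(nb)) { fg[v] = 0; changed = true; }
    }
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = fg[i] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// Euclidean distance transform (distance of foreground voxels to the nearest
// background voxel), Felzenszwalb-Huttenlocher separable parabola method,
// anisotropic spacing aware.
// ---------------------------------------------------------------------------

static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 int n, double s) {
  // squared distance transform of sampled function f on grid with pitch s
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0;
  zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  const double s2 = s * s;
  for (int q = 1; q < n; ++q) {
    double sq = (double)q * q * s2 + f[q];
    double sv = (double)v[k] * v[k] * s2 + f[v[k]];
    double sthr = ((sq - sv) / (2.0 * s2 * (q - v[k])));
    while (sthr <= zb[k]) {
      --k;
      sv = (double)v[k] * v[k] * s2 + f[v[k]];
      sthr = ((sq - sv) / (2.0 * s2 * (q - v[k])));
    }
    ++k;
    v[k] = q;
    zb[k] = sthr;
    zb[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = (double)(q - v[k]) * (q - v[k]) * s2;
    d[q] = dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = 1e30;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? INF : 0.0;

  std::vector<double> f, d;
  // x pass
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = g[lin(x, y, z, nx, ny)];
      dt1d(f, d, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) g[lin(x, y, z, nx, ny)] = d[x];
    }
  // y pass
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = g[lin(x, y, z, nx, ny)];
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) g[lin(x, y, z, nx, ny)] = d[y];
    }
  // z pass
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = g[lin(x, y, z, nx, ny)];
      dt1d(f, d, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) g[lin(x, y, z, nx, ny)] = d[z];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian convolution, reflective boundaries, normalized kernels.
// ---------------------------------------------------------------------------

static void conv_axis(std::vector<double> &a, int nx, int ny, int nz,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * rad + 1);
  double s = 0;
  for (int i = -rad; i <= rad; ++i) {
    ker[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += ker[i + rad];
  }
  for (size_t i = 0; i < ker.size(); ++i) ker[i] /= s;

  int nax = axis == 0 ? nx : (axis == 1 ? ny : nz);
  std::vector<double> line(nax), out(nax);
  auto idx = [&](int i, int j, int k) {
    if (axis == 0) return lin(i, j, k, nx, ny);
    if (axis == 1) return lin(j, i, k, nx, ny);
    return lin(j, k, i, nx, ny);
  };
  int n1 = axis == 0 ? ny : nx;
  int n2 = axis == 2 ? ny : nz;
  for (int k = 0; k < n2; ++k)
    for (int j = 0; j < n1; ++j) {
      for (int i = 0; i < nax; ++i) line[i] = a[idx(i, j, k)];
      for (int i = 0; i < nax; ++i) {
        double acc = 0;
        for (int t = -rad; t <= rad; ++t) {
          int p = i + t;
          if (p < 0) p = -p - 1;               // reflect
          if (p >= nax) p = 2 * nax - p - 1;
          if (p < 0) p = 0;
          if (p >= nax) p = nax - 1;
          acc += ker[t + rad] * line[p];
        }
        out[i] = acc;
      }
      for (int i = 0; i < nax; ++i) a[idx(i, j, k)] = out[i];
    }
}

// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector arr, IntegerVector dim, NumericVector sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(n);
  for (R_xlen_t i = 0; i < n; ++i) a[i] = arr[i];
  conv_axis(a, nx, ny, nz, 0, sigma_vox[0]);
  conv_axis(a, nx, ny, nz, 1, sigma_vox[1]);
  conv_axis(a, nx, ny, nz, 2, sigma_vox[2]);
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = a[i];
  return out;
}

// ---------------------------------------------------------------------------
// Curvature-driven diffusion: explicit modified-curvature-diffusion update
//   u_t = g(|grad u|) * kappa * |grad u|
// with conductance g(s) = 1 / (1 + (s/K)^2) and kappa|grad u| the standard
// second-order mean-curvature expression. Extrema are clamped to the input
// range each iteration (discrete maximum principle).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_cdd3d(NumericVector arr, IntegerVector dim, int n_iter,
                        double dt, double conductance) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> u(n), v(n);
  double lo = R_PosInf, hi = R_NegInf;
  for (R_xlen_t i = 0; i < n; ++i) {
    u[i] = arr[i];
    if (u[i] < lo) lo = u[i];
    if (u[i] > hi) hi = u[i];
  }
  const double eps = 1e-12;
  const double K2 = conductance * conductance;

  auto at = [&](int x, int y, int z) {
    if (x < 0) x = 0; if (x >= nx) x = nx - 1;
    if (y < 0) y = 0; if (y >= ny) y = ny - 1;
    if (z < 0) z = 0; if (z >= nz) z = nz - 1;
    return u[lin(x, y, z, nx, ny)];
  };

  for (int it = 0; it < n_iter; ++it) {
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          double c = at(x, y, z);
          double xp = at(x + 1, y, z), xm = at(x - 1, y, z);
          double yp = at(x, y + 1, z), ym = at(x, y - 1, z);
          double zp = at(x, y, z + 1), zm = at(x, y, z - 1);
          double ux = 0.5 * (xp - xm), uy = 0.5 * (yp - ym), uz = 0.5 * (zp - zm);
          double uxx = xp - 2 * c + xm, uyy = yp - 2 * c + ym, uzz = zp - 2 * c + zm;
          double uxy = 0.25 * (at(x + 1, y + 1, z) - at(x + 1, y - 1, z)
                               - at(x - 1, y + 1, z) + at(x - 1, y - 1, z));
          double uxz = 0.25 * (at(x + 1, y, z + 1) - at(x + 1, y, z - 1)
                               - at(x - 1, y, z + 1) + at(x - 1, y, z - 1));
          double uyz = 0.25 * (at(x, y + 1, z + 1) - at(x, y + 1, z - 1)
                               - at(x, y - 1, z + 1) + at(x, y - 1, z - 1));
          double g2 = ux * ux + uy * uy + uz * uz;
          double num = uxx * (uy * uy + uz * uz)
                     + uyy * (ux * ux + uz * uz)
                     + uzz * (ux * ux + uy * uy)
                     - 2.0 * (ux * uy * uxy + ux * uz * uxz + uy * uz * uyz);
          double kgrad = g2 > eps ? num / g2 : (uxx + uyy + uzz);
          double g = 1.0 / (1.0 + g2 / K2);
          double nv = c + dt * g * kgrad;
          if (nv < lo) nv = lo;
          if (nv > hi) nv = hi;
          v[lin(x, y, z, nx, ny)] = nv;
        }
    std::swap(u, v);
  }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = u[i];
  return out;
}

// ---------------------------------------------------------------------------
// Sphere rasterization: stamp spheres (voxel centres at (i+0.5)*spacing) into
// an intensity array by voxelwise max, or erase (set 0) when erase = true.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_stamp_spheres(NumericVector arr, IntegerVector dim,
                                NumericVector spacing, NumericMatrix centers,
                                NumericVector radii, double value, bool erase) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out = clone(arr);
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  for (int c = 0; c < centers.nrow(); ++c) {
    const double cx = centers(c, 0), cy = centers(c, 1), cz = centers(c, 2);
    const double r = radii[c];
    if (r <= 0) continue;
    const double r2 = r * r;
    int x0 = std::max(0, (int)std::floor((cx - r) / sx - 0.5));
    int x1 = std::min(nx - 1, (int)std::ceil((cx + r) / sx - 0.5));
    int y0 = std::max(0, (int)std::floor((cy - r) / sy - 0.5));
    int y1 = std::min(ny - 1, (int)std::ceil((cy + r) / sy - 0.5));
    int z0 = std::max(0, (int)std::floor((cz - r) / sz - 0.5));
    int z1 = std::min(nz - 1, (int)std::ceil((cz + r) / sz - 0.5));
    for (int z = z0; z <= z1; ++z) {
      double dz = (z + 0.5) * sz - cz;
      for (int y = y0; y <= y1; ++y) {
        double dy = (y + 0.5) * sy - cy;
        for (int x = x0; x <= x1; ++x) {
          double dx = (x + 0.5) * sx - cx;
          if (dx * dx + dy * dy + dz * dz <= r2) {
            int i = lin(x, y, z, nx, ny);
            if (erase) out[i] = 0.0;
            else if (value > out[i]) out[i] = value;
          }
        }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Local maxima of a scalar field (26-neighbourhood, strictly above threshold,
// >= all neighbours). Returns 1-based linear indices.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_local_max(NumericVector arr, IntegerVector dim, double threshold) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<int> hits;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int v = lin(x, y, z, nx, ny);
        double c = arr[v];
        if (!(c > threshold)) continue;
        bool ismax = true;
        for (int dz = -1; dz <= 1 && ismax; ++dz)
          for (int dy = -1; dy <= 1 && ismax; ++dy)
            for (int dx = -1; dx <= 1 && ismax; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
              if (arr[lin(xx, yy, zz, nx, ny)] > c) ismax = false;
            }
        if (ismax) hits.push_back(v + 1);
      }
  return wrap(hits);
}

// ---------------------------------------------------------------------------
// Skeleton chain extraction. Classifies skeleton voxels by 26-neighbour count
// (1 endpoint, 2 slab, >=3 junction; 0 isolated), clusters 26-adjacent
// junction voxels into single nodes, and walks slab chains between node
// voxels. Returns per-voxel node ids (0 = slab or background) and the chains
// as 1-based linear index paths whose first/last voxels are node voxels.
// Pure slab cycles get one voxel promoted to a node and come back as
// self-loop chains.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_skel_chains(LogicalVector skel, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;

  std::vector<int> o26x, o26y, o26z;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        o26x.push_back(dx); o26y.push_back(dy); o26z.push_back(dz);
      }

  auto neighbours = [&](int v, std::vector<int> &out) {
    out.clear();
    int z = v / (nx * ny), r = v % (nx * ny), y = r / nx, x = r % nx;
    for (int k = 0; k < 26; ++k) {
      int xx = x + o26x[k], yy = y + o26y[k], zz = z + o26z[k];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
      int w = lin(xx, yy, zz, nx, ny);
      if (skel[w]) out.push_back(w);
    }
  };

  // neighbour counts
  std::vector<int> fgidx;
  std::vector<int> deg(n, -1);
  std::vector<int> nb;
  for (R_xlen_t v = 0; v < n; ++v) {
    if (!skel[v]) continue;
    fgidx.push_back((int)v);
    neighbours((int)v, nb);
    deg[v] = (int)nb.size();
  }

  // node ids: cluster junction voxels (deg >= 3) by 26-adjacency
  std::vector<int> nodeid(n, 0);
  int nid = 0;
  std::vector<int> stack;
  for (size_t s = 0; s < fgidx.size(); ++s) {
    int v = fgidx[s];
    if (deg[v] < 3 || nodeid[v] != 0) continue;
    ++nid;
    nodeid[v] = nid;
    stack.clear(); stack.push_back(v);
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      neighbours(u, nb);
      for (size_t k = 0; k < nb.size(); ++k) {
        int w = nb[k];
        if (deg[w] >= 3 && nodeid[w] == 0) { nodeid[w] = nid; stack.push_back(w); }
      }
    }
  }
  // endpoints and isolated voxels are singleton nodes
  for (size_t s = 0; s < fgidx.size(); ++s) {
    int v = fgidx[s];
    if ((deg[v] == 1 || deg[v] == 0) && nodeid[v] == 0) nodeid[v] = ++nid;
  }

  std::vector<unsigned char> used(n, 0); // slab voxels consumed by a chain
  std::vector<std::vector<int> > chains;

  std::vector<int> nbv, nbw;
  // chains starting at node voxels
  for (size_t s = 0; s < fgidx.size(); ++s) {
    int v = fgidx[s];
    if (nodeid[v] == 0) continue;
    neighbours(v, nbv);
    for (size_t k = 0; k < nbv.size(); ++k) {
      int w = nbv[k];
      if (nodeid[w] != 0) {
        // direct node-node contact; same cluster => internal, skip
        if (nodeid[w] == nodeid[v]) continue;
        if (w < v) continue; // dedupe
        std::vector<int> ch; ch.push_back(v); ch.push_back(w);
        chains.push_back(ch);
        continue;
      }
      if (used[w]) continue;
      // walk the slab chain
      std::vector<int> ch;
      ch.push_back(v);
      int prev = v, cur = w;
      while (true) {
        ch.push_back(cur);
        used[cur] = 1;
        if (nodeid[cur] != 0) break; // reached a node voxel
        neighbours(cur, nbw);
        int nxt = -1;
        for (size_t j = 0; j < nbw.size(); ++j) {
          int u = nbw[j];
          if (u == prev) continue;
          if (nodeid[u] != 0) { nxt = u; break; }
          if (!used[u]) { nxt = u; }
        }
        if (nxt < 0) break; // dead end (shouldn't happen for clean skeletons)
        prev = cur; cur = nxt;
        if (nodeid[cur] != 0) { ch.push_back(cur); break; }
      }
      chains.push_back(ch);
    }
  }

  // leftover slab voxels = pure cycles: promote one voxel per cycle to a node
  for (size_t s = 0; s < fgidx.size(); ++s) {
    int v = fgidx[s];
    if (nodeid[v] != 0 || used[v] || deg[v] != 2) continue;
    nodeid[v] = ++nid;
    std::vector<int> ch;
    ch.push_back(v);
    neighbours(v, nbv);
    int prev = v, cur = nbv[0];
    while (cur != v) {
      ch.push_back(cur);
      used[cur] = 1;
      neighbours(cur, nbw);
      int nxt = -1;
      for (size_t j = 0; j < nbw.size(); ++j) {
        if (nbw[j] != prev) { nxt = nbw[j]; break; }
      }
      if (nxt < 0) break;
      prev = cur; cur = nxt;
    }
    ch.push_back(v);
    chains.push_back(ch);
  }

  // package chains (convert to 1-based)
  List chlist(chains.size());
  for (size_t i = 0; i < chains.size(); ++i) {
    IntegerVector c(chains[i].size());
    for (size_t j = 0; j < chains[i].size(); ++j) c[j] = chains[i][j] + 1;
    chlist[i] = c;
  }
  IntegerVector ids(n);
  for (R_xlen_t i = 0; i < n; ++i) ids[i] = nodeid[i];
  return List::create(_["node_id"] = ids, _["chains"] = chlist,
                      _["n_nodes"] = nid);
}
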