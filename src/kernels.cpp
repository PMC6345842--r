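#include <Rcpp.h>
#include <array>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Linear index helpers for column-major 3D arrays (R layout).
static inline int lin(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher 2012),
// three separable passes of the 1D squared-distance transform. Handles
// anisotropic voxel spacing by scaling each axis by its physical step.
// ---------------------------------------------------------------------------

// Large finite sentinel for "no site": keeps the parabola arithmetic finite
// while dominating any real squared distance in the grid.
static const double DT_BIG = 1e20;

// 1D squared distance transform over samples at physical step h.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double h) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    double xq = q * h;
    double s = ((f[q] + xq * xq) - (f[v[k]] + (v[k] * h) * (v[k] * h))) /
               (2 * xq - 2 * v[k] * h);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + xq * xq) - (f[v[k]] + (v[k] * h) * (v[k] * h))) /
          (2 * xq - 2 * v[k] * h);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double xq = q * h;
    while (z[k + 1] < xq) k++;
    double xv = v[k] * h;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector site, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector d(site.size());
  for (int i = 0; i < site.size(); i++) d[i] = site[i] ? 0.0 : DT_BIG;

  // pass along x
  {
    std::vector<double> f(nx), out(nx);
    for (int k = 0; k < nz; k++)
      for (int j = 0; j < ny; j++) {
        for (int i = 0; i < nx; i++) f[i] = d[lin(i, j, k, nx, ny)];
        dt1d(f, out, nx, spacing[0]);
        for (int i = 0; i < nx; i++) d[lin(i, j, k, nx, ny)] = out[i];
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), out(ny);
    for (int k = 0; k < nz; k++)
      for (int i = 0; i < nx; i++) {
        for (int j = 0; j < ny; j++) f[j] = d[lin(i, j, k, nx, ny)];
        dt1d(f, out, ny, spacing[1]);
        for (int j = 0; j < ny; j++) d[lin(i, j, k, nx, ny)] = out[j];
      }
  }
  // pass along z
  {
    std::vector<double> f(nz), out(nz);
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        for (int k = 0; k < nz; k++) f[k] = d[lin(i, j, k, nx, ny)];
        dt1d(f, out, nz, spacing[2]);
        for (int k = 0; k < nz; k++) d[lin(i, j, k, nx, ny)] = out[k];
      }
  }
  return d;
}

// ---------------------------------------------------------------------------
// Connected-component labelling of equal-valued zones (union-find).
// Voxels with value 0 are background. Two voxels join a zone when they hold
// the same value and are 26- (default) or 6-connected.
// ---------------------------------------------------------------------------

static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// [[Rcpp::export]]
IntegerVector cpp_label_zones(IntegerVector g, IntegerVector dim, bool conn26) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = g.size();
  std::vector<int> parent(n);
  for (int i = 0; i < n; i++) parent[i] = i;

  // backward half of the neighbourhood
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 0; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (dz == 0 && (dy > 0 || (dy == 0 && dx >= 0))) continue;
        int ad = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (!conn26 && ad != 1) continue;
        offs.push_back({dx, dy, dz});
      }

  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        int p = lin(i, j, k, nx, ny);
        if (g[p] == 0) continue;
        for (auto& o : offs) {
          int ii = i + o[0], jj = j + o[1], kk = k + o[2];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          int q = lin(ii, jj, kk, nx, ny);
          if (g[q] == g[p]) {
            int rp = uf_find(parent, p), rq = uf_find(parent, q);
            if (rp != rq) parent[rp] = rq;
          }
        }
      }

  IntegerVector lab(n);
  std::vector<int> remap(n, 0);
  int next = 0;
  for (int p = 0; p < n; p++) {
    if (g[p] == 0) { lab[p] = 0; continue; }
    int r = uf_find(parent, p);
    if (remap[r] == 0) remap[r] = ++next;
    lab[p] = remap[r];
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Grey level run extraction along one lattice direction. Voxels with value 0
// (outside the ROI) break runs and are never counted. Returns one row per
// run: (grey level, run length).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_runs(IntegerVector g, IntegerVector dim, IntegerVector dir) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int dx = dir[0], dy = dir[1], dz = dir[2];
  std::vector<int> greys, lens;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        int p = lin(i, j, k, nx, ny);
        if (g[p] == 0) continue;
        // run start: previous voxel along dir is out of grid or different
        int pi = i - dx, pj = j - dy, pk = k - dz;
        bool prev_in = pi >= 0 && pj >= 0 && pk >= 0 &&
                       pi < nx && pj < ny && pk < nz;
        if (prev_in && g[lin(pi, pj, pk, nx, ny)] == g[p]) continue;
        int len = 1;
        int ci = i + dx, cj = j + dy, ck = k + dz;
        while (ci >= 0 && cj >= 0 && ck >= 0 && ci < nx && cj < ny && ck < nz &&
               g[lin(ci, cj, ck, nx, ny)] == g[p]) {
          len++;
          ci += dx; cj += dy; ck += dz;
        }
        greys.push_back(g[p]);
        lens.push_back(len);
      }
  IntegerMatrix out(greys.size(), 2);
  for (size_t r = 0; r < greys.size(); r++) {
    out(r, 0) = greys[r];
    out(r, 1) = lens[r];
  }
  return out;
}

// ---------------------------------------------------------------------------
// 3D SLIC supervoxels. Cluster centres start on a regular grid with physical
// interval S mm; assignment minimises D^2 = dI^2 + m^2 * (ds/S)^2 where dI is
// the intensity difference (HU), ds the spatial distance (mm) and m the
// compactness. Deterministic: no random initialisation.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_slic(NumericVector img, IntegerVector dim,
                       NumericVector spacing, double S, double compactness,
                       int iters) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = img.size();
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];

  // initial centres on a regular grid (physical mm), at least one per axis
  std::vector<double> cx, cy, cz, cv;
  for (double z = S / 2; z < nz * sz || cz.empty(); z += S) {
    if (z >= nz * sz && !cz.empty()) break;
    for (double y = S / 2; y < ny * sy || cy.empty(); y += S) {
      if (y >= ny * sy && !cy.empty()) break;
      for (double x = S / 2; x < nx * sx || cx.empty(); x += S) {
        if (x >= nx * sx && !cx.empty()) break;
        int i = std::min(nx - 1, (int)(x / sx));
        int j = std::min(ny - 1, (int)(y / sy));
        int k = std::min(nz - 1, (int)(z / sz));
        cx.push_back((i + 0.5) * sx);
        cy.push_back((j + 0.5) * sy);
        cz.push_back((k + 0.5) * sz);
        cv.push_back(img[lin(i, j, k, nx, ny)]);
      }
    }
  }
  int K = cx.size();
  std::vector<int> lab(n, -1);
  std::vector<double> best(n, std::numeric_limits<double>::infinity());
  const double m2S2 = (compactness * compactness) / (S * S);

  for (int it = 0; it < iters; it++) {
    std::fill(best.begin(), best.end(),
              std::numeric_limits<double>::infinity());
    for (int c = 0; c < K; c++) {
      int i0 = std::max(0, (int)std::floor((cx[c] - S) / sx));
      int i1 = std::min(nx - 1, (int)std::ceil((cx[c] + S) / sx));
      int j0 = std::max(0, (int)std::floor((cy[c] - S) / sy));
      int j1 = std::min(ny - 1, (int)std::ceil((cy[c] + S) / sy));
      int k0 = std::max(0, (int)std::floor((cz[c] - S) / sz));
      int k1 = std::min(nz - 1, (int)std::ceil((cz[c] + S) / sz));
      for (int k = k0; k <= k1; k++)
        for (int j = j0; j <= j1; j++)
          for (int i = i0; i <= i1; i++) {
            int p = lin(i, j, k, nx, ny);
            double px = (i + 0.5) * sx, py = (j + 0.5) * sy,
                   pz = (k + 0.5) * sz;
            double dI = img[p] - cv[c];
            double ds2 = (px - cx[c]) * (px - cx[c]) +
                         (py - cy[c]) * (py - cy[c]) +
                         (pz - cz[c]) * (pz - cz[c]);
            double D = dI * dI + m2S2 * ds2;
            if (D < best[p]) {
              best[p] = D;
              lab[p] = c;
            }
          }
    }
    // update centres
    std::vector<double> ax(K, 0), ay(K, 0), az(K, 0), av(K, 0);
    std::vector<int> cnt(K, 0);
    for (int k = 0; k < nz; k++)
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++) {
          int p = lin(i, j, k, nx, ny);
          int c = lab[p];
          if (c < 0) continue;
          ax[c] += (i + 0.5) * sx;
          ay[c] += (j + 0.5) * sy;
          az[c] += (k + 0.5) * sz;
          av[c] += img[p];
          cnt[c]++;
        }
    for (int c = 0; c < K; c++) {
      if (cnt[c] == 0) continue;
      cx[c] = ax[c] / cnt[c];
      cy[c] = ay[c] / cnt[c];
      cz[c] = az[c] / cnt[c];
      cv[c] = av[c] / cnt[c];
    }
  }

  // any voxel outside all windows (cannot happen with grid init, but guard):
  // assign to nearest centre spatially
  IntegerVector out(n);
  for (int p = 0; p < n; p++) out[p] = lab[p] + 1;
  return out;
}
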