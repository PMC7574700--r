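// 3D Euclidean distance transform and inscribed-sphere local thickness for
// binary voxel volumes. The EDT uses the separable lower-envelope algorithm
// (binary two-sweep along x, then generalized parabola passes along y and z);
// local thickness paints spheres from distance-ridge voxels, in decreasing
// radius order, and assigns each covered foreground voxel the largest sphere
// diameter that contains it.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// generalized 1D squared distance transform (Felzenszwalb-Huttenlocher)
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -1e30;
  z[1] = 1e30;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double BIG = 1e30;
  NumericVector out(mask.size());

  // pass 1: binary two-sweep along x (fast, avoids BIG in the parabola pass)
  const double cap = (double)(nx + ny + nz + 2);
  for (int z = 0; z < nz; z++) {
    for (int y = 0; y < ny; y++) {
      const R_xlen_t off = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      double run = cap;
      for (int x = 0; x < nx; x++) {
        run = mask[off + x] ? run + 1.0 : 0.0;
        out[off + x] = run;
      }
      run = cap;
      for (int x = nx - 1; x >= 0; x--) {
        run = mask[off + x] ? run + 1.0 : 0.0;
        if (run < out[off + x]) out[off + x] = run;
      }
      for (int x = 0; x < nx; x++) {
        double d = std::min(out[off + x], cap);
        out[off + x] = d * d;
      }
    }
  }

  // pass 2: along y
  {
    std::vector<double> f(ny), d(ny), zbuf(ny + 1);
    std::vector<int> v(ny);
    for (int z = 0; z < nz; z++) {
      for (int x = 0; x < nx; x++) {
        const R_xlen_t base = (R_xlen_t)z * nx * ny + x;
        for (int y = 0; y < ny; y++) f[y] = out[base + (R_xlen_t)y * nx];
        dt1d(f, d, ny, v, zbuf);
        for (int y = 0; y < ny; y++) out[base + (R_xlen_t)y * nx] = d[y];
      }
    }
  }

  // pass 3: along z
  {
    std::vector<double> f(nz), d(nz), zbuf(nz + 1);
    std::vector<int> v(nz);
    const R_xlen_t plane = (R_xlen_t)nx * ny;
    for (int y = 0; y < ny; y++) {
      for (int x = 0; x < nx; x++) {
        const R_xlen_t base = (R_xlen_t)y * nx + x;
        for (int z = 0; z < nz; z++) f[z] = out[base + (R_xlen_t)z * plane];
        dt1d(f, d, nz, v, zbuf);
        for (int z = 0; z < nz; z++) out[base + (R_xlen_t)z * plane] = d[z];
      }
    }
  }

  (void)BIG;
  return out;
}

// distance-ridge voxels: foreground voxels whose squared EDT is >= that of
// every 26-neighbor (out-of-bounds neighbors count as background, 0)
// [[Rcpp::export]]
IntegerVector distance_ridge_cpp(NumericVector edt_sq, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  std::vector<int> ridge;
  for (int z = 0; z < nz; z++) {
    for (int y = 0; y < ny; y++) {
      for (int x = 0; x < nx; x++) {
        const R_xlen_t i = (R_xlen_t)z * plane + (R_xlen_t)y * nx + x;
        const double c = edt_sq[i];
        if (c <= 0) continue;
        bool is_ridge = true;
        for (int dz = -1; dz <= 1 && is_ridge; dz++) {
          const int zz = z + dz;
          if (zz < 0 || zz >= nz) continue;
          for (int dy = -1; dy <= 1 && is_ridge; dy++) {
            const int yy = y + dy;
            if (yy < 0 || yy >= ny) continue;
            for (int dx = -1; dx <= 1; dx++) {
              if (!dx && !dy && !dz) continue;
              const int xx = x + dx;
              if (xx < 0 || xx >= nx) continue;
              if (edt_sq[(R_xlen_t)zz * plane + (R_xlen_t)yy * nx + xx] > c) {
                is_ridge = false;
                break;
              }
            }
          }
        }
        if (is_ridge) ridge.push_back((int)(i + 1)); // 1-based for R
      }
    }
  }
  return wrap(ridge);
}

// [[Rcpp::export]]
NumericVector local_thickness_cpp(LogicalVector mask, NumericVector edt_sq,
                                  IntegerVector ridge, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  NumericVector th(mask.size());

  // sort ridge voxels by decreasing radius so larger spheres paint first
  std::vector<std::pair<double, int>> order;
  order.reserve(ridge.size());
  for (int k = 0; k < ridge.size(); k++) {
    const R_xlen_t i = (R_xlen_t)ridge[k] - 1;
    order.push_back(std::make_pair(edt_sq[i], (int)i));
  }
  std::sort(order.begin(), order.end(),
            [](const std::pair<double, int>& a,
               const std::pair<double, int>& b) { return a.first > b.first; });

  for (size_t k = 0; k < order.size(); k++) {
    const double r2 = order[k].first;
    const R_xlen_t c = order[k].second;
    const double r = std::sqrt(r2);
    const double diam = 2.0 * r;
    if (th[c] >= diam) continue; // already inside an equal-or-larger sphere
    const int cz = (int)(c / plane);
    const int cy = (int)((c - (R_xlen_t)cz * plane) / nx);
    const int cx = (int)(c - (R_xlen_t)cz * plane - (R_xlen_t)cy * nx);
    const int ri = (int)std::floor(r);
    for (int dz = -ri; dz <= ri; dz++) {
      const int zz = cz + dz;
      if (zz < 0 || zz >= nz) continue;
      for (int dy = -ri; dy <= ri; dy++) {
        const int yy = cy + dy;
        if (yy < 0 || yy >= ny) continue;
        const double d2xy = (double)dz * dz + (double)dy * dy;
        if (d2xy > r2) continue;
        const R_xlen_t rowbase = (R_xlen_t)zz * plane + (R_xlen_t)yy * nx;
        for (int dx = -ri; dx <= ri; dx++) {
          const int xx = cx + dx;
          if (xx < 0 || xx >= nx) continue;
          if (d2xy + (double)dx * dx > r2) continue;
          const R_xlen_t j = rowbase + xx;
          if (mask[j] && th[j] < diam) th[j] = diam;
        }
      }
    }
  }

  // any foreground voxel missed by every sphere falls back to its own EDT
  for (R_xlen_t i = 0; i < mask.size(); i++) {
    if (mask[i] && th[i] <= 0) {
      th[i] = 2.0 * std::sqrt(edt_sq[i]);
    }
  }
  return th;
}
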