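#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher),
// with physical sample step `step` (mm between neighbouring voxel centers).
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double step, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  double s2 = step * step;
  for (int q = 1; q < n; ++q) {
    double fq = f[q] + s2 * q * q;
    while (true) {
      double fv = f[v[k]] + s2 * v[k] * v[k];
      double s = (fq - fv) / (2.0 * s2 * (q - v[k]));
      if (s <= z[k]) {
        --k;
      } else {
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = std::numeric_limits<double>::infinity();
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = s2 * (q - v[k]) * (q - v[k]);
    d[q] = dq + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest TRUE
// voxel of `mask`, honouring anisotropic voxel spacing. Voxels with no TRUE
// voxel anywhere give Inf.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  // large finite sentinel: infinities would produce NaN in the envelope
  // intersection arithmetic
  const double INF = 1e30;
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

  // pass along x (fastest-varying index)
  {
    std::vector<double> f(nx), d(nx);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
        for (int x = 0; x < nx; ++x) f[x] = out[base + x];
        dt1d(f, d, spacing[0], nx);
        for (int x = 0; x < nx; ++x) out[base + x] = d[x];
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), d(ny);
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = (R_xlen_t)z * nx * ny + x;
        for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)y * nx];
        dt1d(f, d, spacing[1], ny);
        for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = d[y];
      }
  }
  // pass along z
  {
    std::vector<double> f(nz), d(nz);
    R_xlen_t nxy = (R_xlen_t)nx * ny;
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = (R_xlen_t)y * nx + x;
        for (int z = 0; z < nz; ++z) f[z] = out[base + (R_xlen_t)z * nxy];
        dt1d(f, d, spacing[2], nz);
        for (int z = 0; z < nz; ++z) out[base + (R_xlen_t)z * nxy] = d[z];
      }
  }
  for (R_xlen_t i = 0; i < n; ++i)
    if (out[i] >= 1e29) out[i] = R_PosInf;
  return out;
}

// 26-connectivity component labelling of a logical 3D array.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int current = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || lab[start] != 0) continue;
    ++current;
    stack.push_back(start);
    lab[start] = current;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              continue;
            R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
            if (mask[w] && lab[w] == 0) {
              lab[w] = current;
              stack.push_back(w);
            }
          }
    }
  }
  lab.attr("n_components") = current;
  return lab;
}
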