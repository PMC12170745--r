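#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// The 13 unique 3D directions (one per axis pair, opposite directions
// counted once), matching the usual run-length convention.
static const int DIRS[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

// Gray-level run-length matrices for a discretized ROI.
// `labels`: integer array, 0 outside the ROI, 1..n_levels inside.
// Returns a list of 13 matrices (n_levels x max_run); a gap in the ROI
// terminates a run.
// [[Rcpp::export]]
List cpp_glrlm(IntegerVector labels, IntegerVector dims, int n_levels) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  int max_run = nx + ny + nz;  // safe upper bound on any straight run
  List out(13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    IntegerMatrix P(n_levels, max_run);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          R_xlen_t v = (R_xlen_t)z * nxy + (R_xlen_t)y * nx + x;
          int g = labels[v];
          if (g <= 0) continue;
          // start of a maximal run: predecessor missing or different level
          int px = x - dx, py = y - dy, pz = z - dz;
          if (px >= 0 && px < nx && py >= 0 && py < ny && pz >= 0 && pz < nz) {
            R_xlen_t pv = (R_xlen_t)pz * nxy + (R_xlen_t)py * nx + px;
            if (labels[pv] == g) continue;
          }
          int len = 1;
          int cx = x + dx, cy = y + dy, cz = z + dz;
          while (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 &&
                 cz < nz) {
            R_xlen_t cv = (R_xlen_t)cz * nxy + (R_xlen_t)cy * nx + cx;
            if (labels[cv] != g) break;
            ++len;
            cx += dx; cy += dy; cz += dz;
          }
          P(g - 1, len - 1) += 1;
        }
    out[d] = P;
  }
  return out;
}

// Maximum pairwise Euclidean distance between rows of an n x 3 coordinate
// matrix (mm). Returns 0 for a single point.
// [[Rcpp::export]]
double cpp_max_pairwise_dist(NumericMatrix coords) {
  int n = coords.nrow();
  double best = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    for (int j = i + 1; j < n; ++j) {
      double dx = xi - coords(j, 0);
      double dy = yi - coords(j, 1);
      double dz = zi - coords(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  }
  return std::sqrt(best);
}

// Index (1-based) of the nearest center for every query point.
// [[Rcpp::export]]
IntegerVector cpp_nearest_center(NumericMatrix points, NumericMatrix centers) {
  int n = points.nrow(), m = centers.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int arg = 1;
    for (int j = 0; j < m; ++j) {
      double dx = points(i, 0) - centers(j, 0);
      double dy = points(i, 1) - centers(j, 1);
      double dz = points(i, 2) - centers(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; arg = j + 1; }
    }
    out[i] = arg;
  }
  return out;
}
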