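#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

static const double EDT_INF = std::numeric_limits<double>::infinity();

// Lower-envelope-of-parabolas 1-D squared distance transform
// (Felzenszwalb & Huttenlocher), on samples at physical positions
// i * s for i = 0..n-1.  f holds squared distances from a previous
// pass (EDT_INF where no seed has been seen); d receives the result.
static void dt1d(const double* f, double* d, int n, double s,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = -1;
  for (int q = 0; q < n; q++) {
    if (f[q] == EDT_INF) continue;
    double xq = q * s;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -EDT_INF; z[1] = EDT_INF;
      continue;
    }
    double sint;
    for (;;) {                 // z[0] = -Inf, so the envelope never empties
      double xv = v[k] * s;
      sint = (f[q] + xq * xq - f[v[k]] - xv * xv) / (2.0 * xq - 2.0 * xv);
      if (sint <= z[k]) k--; else break;
    }
    k++; v[k] = q; z[k] = sint; z[k + 1] = EDT_INF;
  }
  if (k < 0) {                 // whole line has no seed
    for (int q = 0; q < n; q++) d[q] = EDT_INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; q++) {
    double xq = q * s;
    while (z[j + 1] < xq) j++;
    double dx = xq - v[j] * s;
    d[q] = dx * dx + f[v[j]];
  }
}

// Squared Euclidean distance (physical mm) from every voxel center to
// the nearest true voxel center of `mask` on a grid with per-axis
// spacing `spacing` (mm).  Column-major 3-D layout, dims = c(nx,ny,nz).
// [[Rcpp::export(name = ".cpp_squared_edt")]]
NumericVector cpp_squared_edt(LogicalVector mask, IntegerVector dims,
                              NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  NumericVector out(n);
  double* d = REAL(out);
  for (R_xlen_t i = 0; i < n; i++) d[i] = mask[i] ? 0.0 : EDT_INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), g(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (stride 1)
  for (int kz = 0; kz < nz; kz++)
    for (int ky = 0; ky < ny; ky++) {
      double* line = d + (R_xlen_t)kz * nx * ny + (R_xlen_t)ky * nx;
      dt1d(line, g.data(), nx, spacing[0], v, z);
      std::copy(g.begin(), g.begin() + nx, line);
    }
  // pass along y (stride nx)
  for (int kz = 0; kz < nz; kz++)
    for (int kx = 0; kx < nx; kx++) {
      double* base = d + (R_xlen_t)kz * nx * ny + kx;
      for (int ky = 0; ky < ny; ky++) f[ky] = base[(R_xlen_t)ky * nx];
      dt1d(f.data(), g.data(), ny, spacing[1], v, z);
      for (int ky = 0; ky < ny; ky++) base[(R_xlen_t)ky * nx] = g[ky];
    }
  // pass along z (stride nx*ny)
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int ky = 0; ky < ny; ky++)
    for (int kx = 0; kx < nx; kx++) {
      double* base = d + (R_xlen_t)ky * nx + kx;
      for (int kz = 0; kz < nz; kz++) f[kz] = base[(R_xlen_t)kz * sz];
      dt1d(f.data(), g.data(), nz, spacing[2], v, z);
      for (int kz = 0; kz < nz; kz++) base[(R_xlen_t)kz * sz] = g[kz];
    }
  return out;
}
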