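#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1-D squared distance transform (lower envelope of parabolas) with a
// physical step size, so anisotropic voxel spacing is handled exactly.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double step) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[k]] == INF) { v[k] = q; z[k] = -INF; z[k + 1] = INF; continue; }
    double xq = q * step;
    double s;
    while (true) {
      double xv = v[k] * step;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * step;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * step;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel centre to the nearest
// TRUE voxel centre. Voxels where mask is TRUE get 0.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double INF = std::numeric_limits<double>::infinity();
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

  std::vector<double> f, d;
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, d, spacing[0]);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j)
        f[j] = out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      dt1d(f, d, spacing[1]);
      for (int j = 0; j < ny; ++j)
        out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = d[j];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k)
        f[k] = out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      dt1d(f, d, spacing[2]);
      for (int k = 0; k < nz; ++k)
        out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = d[k];
    }
  return out;
}
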