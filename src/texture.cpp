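#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// All accumulators take an integer volume `bins` where 0 marks voxels
// outside the region and 1..Ng are discretized gray levels. Direction-merged
// aggregation: counts are summed over the 13 unique 3-D offsets before any
// feature is computed.

static const int OFF13[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline R_xlen_t idx3(int i, int j, int k, int nx, int ny) {
  return i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
}

// Symmetric gray-level co-occurrence counts, distance 1, merged over the 13
// unique directions (each pair counted in both orders).
// [[Rcpp::export]]
NumericMatrix glcm_counts_cpp(IntegerVector bins, IntegerVector dim, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix P(ng, ng);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int a = bins[idx3(i, j, k, nx, ny)];
        if (a == 0) continue;
        for (int d = 0; d < 13; ++d) {
          int ii = i + OFF13[d][0], jj = j + OFF13[d][1], kk = k + OFF13[d][2];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          int b = bins[idx3(ii, jj, kk, nx, ny)];
          if (b == 0) continue;
          P(a - 1, b - 1) += 1.0;
          P(b - 1, a - 1) += 1.0;
        }
      }
  return P;
}

// Gray-level run-length counts merged over the 13 unique directions.
// A run is a maximal straight sequence of in-region voxels sharing a level.
// [[Rcpp::export]]
NumericMatrix glrlm_counts_cpp(IntegerVector bins, IntegerVector dim, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  int maxext = std::max(nx, std::max(ny, nz));
  NumericMatrix P(ng, maxext);
  for (int d = 0; d < 13; ++d) {
    const int dx = OFF13[d][0], dy = OFF13[d][1], dz = OFF13[d][2];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int a = bins[idx3(i, j, k, nx, ny)];
          if (a == 0) continue;
          // run starts here iff the previous voxel along d is not the same level
          int pi = i - dx, pj = j - dy, pk = k - dz;
          if (pi >= 0 && pj >= 0 && pk >= 0 && pi < nx && pj < ny && pk < nz &&
              bins[idx3(pi, pj, pk, nx, ny)] == a)
            continue;
          int len = 1;
          int ci = i + dx, cj = j + dy, ck = k + dz;
          while (ci >= 0 && cj >= 0 && ck >= 0 && ci < nx && cj < ny && ck < nz &&
                 bins[idx3(ci, cj, ck, nx, ny)] == a) {
            ++len; ci += dx; cj += dy; ck += dz;
          }
          P(a - 1, len - 1) += 1.0;
        }
  }
  return P;
}

// Gray-level size-zone enumeration: 26-connected components of constant
// level. Returns a two-column matrix (level, zone size in voxels).
// [[Rcpp::export]]
IntegerMatrix glszm_zones_cpp(IntegerVector bins, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> glv, szv;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (seen[s] || bins[s] == 0) continue;
    int a = bins[s];
    int size = 0;
    stack.clear();
    stack.push_back(s);
    seen[s] = 1;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      ++size;
      int ci = cur % nx;
      int cj = (cur / nx) % ny;
      int ck = cur / ((R_xlen_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int ii = ci + dx, jj = cj + dy, kk = ck + dz;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            R_xlen_t t = idx3(ii, jj, kk, nx, ny);
            if (!seen[t] && bins[t] == a) { seen[t] = 1; stack.push_back(t); }
          }
    }
    glv.push_back(a);
    szv.push_back(size);
  }
  IntegerMatrix out((int)glv.size(), 2);
  for (int r = 0; r < (int)glv.size(); ++r) {
    out(r, 0) = glv[r];
    out(r, 1) = szv[r];
  }
  return out;
}

// Gray-level dependence counts: dependence of a voxel is 1 plus the number
// of in-region 26-neighbours whose level differs by at most alpha.
// Columns index dependence 1..27.
// [[Rcpp::export]]
NumericMatrix gldm_counts_cpp(IntegerVector bins, IntegerVector dim, int ng,
                              int alpha) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix P(ng, 27);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int a = bins[idx3(i, j, k, nx, ny)];
        if (a == 0) continue;
        int dep = 1;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int ii = i + dx, jj = j + dy, kk = k + dz;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
                continue;
              int b = bins[idx3(ii, jj, kk, nx, ny)];
              if (b != 0 && std::abs(b - a) <= alpha) ++dep;
            }
        P(a - 1, dep - 1) += 1.0;
      }
  return P;
}

// Neighbourhood gray-tone difference accumulators: for each level i, n_i
// voxels and s_i = sum over those voxels of |level - mean(in-region
// 26-neighbour levels)|. Voxels with no in-region neighbour are skipped.
// [[Rcpp::export]]
NumericMatrix ngtdm_stats_cpp(IntegerVector bins, IntegerVector dim, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 2); // col 0: n_i, col 1: s_i
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int a = bins[idx3(i, j, k, nx, ny)];
        if (a == 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int ii = i + dx, jj = j + dy, kk = k + dz;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
                continue;
              int b = bins[idx3(ii, jj, kk, nx, ny)];
              if (b != 0) { sum += b; ++cnt; }
            }
        if (cnt == 0) continue;
        out(a - 1, 0) += 1.0;
        out(a - 1, 1) += std::abs((double)a - sum / cnt);
      }
  return out;
}
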