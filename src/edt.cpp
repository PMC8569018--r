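#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher 2012):
// squared-distance lower envelope of parabolas, one pass per dimension.

static const double INF = std::numeric_limits<double>::infinity();

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF) { v[0] = q; z[1] = INF; continue; }
    double s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    while (k > 0 && s <= z[k]) {
      --k;
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    if (f[v[0]] == INF) { d[q] = INF; continue; }
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Distance (in voxels) from every voxel to the nearest seed voxel.
// seeds: logical array (z, y, x).
// [[Rcpp::export(name = ".edt_cpp")]]
NumericVector edt_cpp(LogicalVector seeds, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = seeds[i] ? 0.0 : INF;

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // along z (stride 1)
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      for (int q = 0; q < nz; ++q) f[q] = g[base + q];
      dt1d(f, d, nz, v, z);
      for (int q = 0; q < nz; ++q) g[base + q] = d[q];
    }
  // along y (stride nz)
  for (int x = 0; x < nx; ++x)
    for (int zi = 0; zi < nz; ++zi) {
      R_xlen_t base = zi + (R_xlen_t)nz * ny * x;
      for (int q = 0; q < ny; ++q) f[q] = g[base + (R_xlen_t)nz * q];
      dt1d(f, d, ny, v, z);
      for (int q = 0; q < ny; ++q) g[base + (R_xlen_t)nz * q] = d[q];
    }
  // along x (stride nz*ny)
  for (int y = 0; y < ny; ++y)
    for (int zi = 0; zi < nz; ++zi) {
      R_xlen_t base = zi + (R_xlen_t)nz * y;
      for (int q = 0; q < nx; ++q) f[q] = g[base + (R_xlen_t)nz * ny * q];
      dt1d(f, d, nx, v, z);
      for (int q = 0; q < nx; ++q) g[base + (R_xlen_t)nz * ny * q] = d[q];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (g[i] == INF) ? R_PosInf : std::sqrt(g[i]);
  out.attr("dim") = dims;
  return out;
}
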