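#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Volumes are (z, y, x) column-major: linear index z + nz*(y + ny*x), 0-based.
// Rotation is about the z axis; detector rows are z, columns are the lateral
// coordinate s. Parallel-beam geometry (telecentric optics).

// [[Rcpp::export(name = ".forward_project_cpp")]]
NumericVector forward_project_cpp(NumericVector vol, IntegerVector dims,
                                  NumericVector angles_rad, int ndet) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int na = angles_rad.size();
  const int nt = ndet;                      // ray samples, 1 voxel apart
  const double cy = 0.5 * (ny - 1), cx = 0.5 * (nx - 1);
  const double cs = 0.5 * (ndet - 1), ct = 0.5 * (nt - 1);
  NumericVector out(static_cast<R_xlen_t>(nz) * ndet * na);
  const double* v = vol.begin();
  double* o = out.begin();

  for (int a = 0; a < na; ++a) {
    const double co = std::cos(angles_rad[a]), si = std::sin(angles_rad[a]);
    for (int j = 0; j < nt; ++j) {
      const double t = j - ct;
      for (int i = 0; i < ndet; ++i) {
        const double s = i - cs;
        const double x = cx + s * co - t * si;
        const double y = cy + s * si + t * co;
        if (x < 0 || x > nx - 1 || y < 0 || y > ny - 1) continue;
        int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
        if (x0 == nx - 1) --x0;
        if (y0 == ny - 1) --y0;
        const double fx = x - x0, fy = y - y0;
        const double w00 = (1 - fy) * (1 - fx), w10 = fy * (1 - fx);
        const double w01 = (1 - fy) * fx,       w11 = fy * fx;
        const double* c00 = v + nz * (y0     + (R_xlen_t)ny * x0);
        const double* c10 = v + nz * (y0 + 1 + (R_xlen_t)ny * x0);
        const double* c01 = v + nz * (y0     + (R_xlen_t)ny * (x0 + 1));
        const double* c11 = v + nz * (y0 + 1 + (R_xlen_t)ny * (x0 + 1));
        double* po = o + nz * (i + (R_xlen_t)ndet * a);
        for (int z = 0; z < nz; ++z)
          po[z] += w00 * c00[z] + w10 * c10[z] + w01 * c01[z] + w11 * c11[z];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nz, ndet, na);
  return out;
}

// Back-project (already filtered) projections onto an (nz, ny, nx) grid.
// Caller applies the pi / n_angles scaling for 360-degree coverage.
// [[Rcpp::export(name = ".backproject_cpp")]]
NumericVector backproject_cpp(NumericVector proj, IntegerVector pdims,
                              NumericVector angles_rad, int ny, int nx) {
  const int nz = pdims[0], ndet = pdims[1];
  const int na = angles_rad.size();
  const double cy = 0.5 * (ny - 1), cx = 0.5 * (nx - 1);
  const double cs = 0.5 * (ndet - 1);
  NumericVector out(static_cast<R_xlen_t>(nz) * ny * nx);
  const double* p = proj.begin();
  double* o = out.begin();

  for (int a = 0; a < na; ++a) {
    const double co = std::cos(angles_rad[a]), si = std::sin(angles_rad[a]);
    const double* pa = p + (R_xlen_t)nz * ndet * a;
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        const double s = (x - cx) * co + (y - cy) * si + cs;
        if (s < 0 || s > ndet - 1) continue;
        int i0 = (int)std::floor(s);
        if (i0 == ndet - 1) --i0;
        const double f = s - i0;
        const double* q0 = pa + (R_xlen_t)nz * i0;
        const double* q1 = q0 + nz;
        double* po = o + nz * (y + (R_xlen_t)ny * x);
        for (int z = 0; z < nz; ++z)
          po[z] += (1 - f) * q0[z] + f * q1[z];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nz, ny, nx);
  return out;
}
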