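#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 26-connected component labeling of a 3D binary mask, BFS flood fill.
// Labels are assigned in raster order of the first-encountered voxel.
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector labels(n);
  std::vector<R_xlen_t> queue;
  int next = 0;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start]) continue;
    ++next;
    labels[start] = next;
    queue.clear();
    queue.push_back(start);
    while (!queue.empty()) {
      R_xlen_t idx = queue.back();
      queue.pop_back();
      int z = idx % nz;
      int y = (idx / nz) % ny;
      int x = idx / ((R_xlen_t)nz * ny);
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx;
        if (xx < 0 || xx >= nx) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dz = -1; dz <= 1; ++dz) {
            int zz = z + dz;
            if (zz < 0 || zz >= nz) continue;
            R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
            if (mask[j] && !labels[j]) {
              labels[j] = next;
              queue.push_back(j);
            }
          }
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}
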