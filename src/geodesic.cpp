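#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Dijkstra shortest paths within a binary mask, 26-neighbor steps weighted by
// Euclidean step length (1, sqrt(2), sqrt(3) voxels). Distances are in voxel
// units; voxels outside the mask (or unreachable) get NA. Predecessors allow
// geodesic path extraction.

// [[Rcpp::export(name = ".geodesic_cpp")]]
List geodesic_cpp(LogicalVector mask, IntegerVector dims, IntegerVector seeds0) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<double> dist(n, R_PosInf);
  std::vector<R_xlen_t> pred(n, -1);

  typedef std::pair<double, R_xlen_t> Item;
  std::priority_queue<Item, std::vector<Item>, std::greater<Item> > pq;
  for (int k = 0; k < seeds0.size(); ++k) {
    R_xlen_t s = seeds0[k];
    if (s < 0 || s >= n || !mask[s]) stop("seed outside mask");
    dist[s] = 0.0;
    pq.push(Item(0.0, s));
  }

  static const double stepLen[4] = {0.0, 1.0, M_SQRT2, 1.7320508075688772};

  while (!pq.empty()) {
    double d = pq.top().first;
    R_xlen_t idx = pq.top().second;
    pq.pop();
    if (d > dist[idx]) continue;
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
          if (dz == 0 && dy == 0 && dx == 0) continue;
          int zz = z + dz;
          if (zz < 0 || zz >= nz) continue;
          R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
          if (!mask[j]) continue;
          double nd = d + stepLen[std::abs(dz) + std::abs(dy) + std::abs(dx)];
          if (nd < dist[j]) {
            dist[j] = nd;
            pred[j] = idx;
            pq.push(Item(nd, j));
          }
        }
      }
    }
  }

  NumericVector outDist(n);
  IntegerVector outPred(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    outDist[i] = (mask[i] && dist[i] < R_PosInf) ? dist[i] : NA_REAL;
    outPred[i] = (pred[i] >= 0) ? (int)pred[i] : NA_INTEGER;  // 0-based
  }
  outDist.attr("dim") = dims;
  return List::create(_["dist"] = outDist, _["pred"] = outPred);
}
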