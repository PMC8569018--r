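#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Distance-ordered homotopic thinning: mask voxels are visited in order of
// increasing distance to the background and deleted when they are simple
// points (deletion preserves topology; Bertrand & Malandain characterization)
// and not curve endpoints. The result is a 1-voxel-wide curve skeleton
// centered on the medial axis.

namespace {

// neighborhood index: (dz+1) + 3*(dy+1) + 9*(dx+1); center = 13
inline int nbIndex(int dz, int dy, int dx) {
  return (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1);
}

// T26: number of 26-components of the object within the 26-neighborhood
static int countObjComponents26(const bool nb[27]) {
  bool seen[27] = {false};
  int comps = 0;
  int stack[27];
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    ++comps;
    int top = 0;
    stack[top++] = i;
    seen[i] = true;
    while (top > 0) {
      int c = stack[--top];
      int cz = c % 3, cy = (c / 3) % 3, cx = c / 9;
      for (int j = 0; j < 27; ++j) {
        if (j == 13 || !nb[j] || seen[j]) continue;
        int jz = j % 3, jy = (j / 3) % 3, jx = j / 9;
        if (std::abs(jz - cz) <= 1 && std::abs(jy - cy) <= 1 &&
            std::abs(jx - cx) <= 1) {
          seen[j] = true;
          stack[top++] = j;
        }
      }
    }
  }
  return comps;
}

// T6: number of 6-components of the background within the 18-neighborhood
// that touch a face neighbor of the center
static int countBgComponents6(const bool nb[27]) {
  // N18 membership: chebyshev distance 1 from center, not a corner
  bool inN18[27], bg[27];
  for (int i = 0; i < 27; ++i) {
    int z = i % 3 - 1, y = (i / 3) % 3 - 1, x = i / 9 - 1;
    int man = std::abs(z) + std::abs(y) + std::abs(x);
    inN18[i] = (i != 13) && man <= 2;  // faces and edges only
    bg[i] = inN18[i] && !nb[i];
  }
  bool seen[27] = {false};
  int comps = 0;
  int stack[27];
  for (int i = 0; i < 27; ++i) {
    if (!bg[i] || seen[i]) continue;
    int iz = i % 3 - 1, iy = (i / 3) % 3 - 1, ix = i / 9 - 1;
    bool touchesFace = (std::abs(iz) + std::abs(iy) + std::abs(ix) == 1);
    int top = 0;
    stack[top++] = i;
    seen[i] = true;
    while (top > 0) {
      int c = stack[--top];
      int cz = c % 3, cy = (c / 3) % 3, cx = c / 9;
      for (int j = 0; j < 27; ++j) {
        if (!bg[j] || seen[j]) continue;
        int jz = j % 3, jy = (j / 3) % 3, jx = j / 9;
        int man = std::abs(jz - cz) + std::abs(jy - cy) + std::abs(jx - cx);
        if (man == 1) {
          seen[j] = true;
          stack[top++] = j;
          int az = jz - 1, ay = jy - 1, ax = jx - 1;
          if (std::abs(az) + std::abs(ay) + std::abs(ax) == 1) touchesFace = true;
        }
      }
    }
    if (touchesFace) ++comps;
  }
  return comps;
}

}  // namespace

// [[Rcpp::export(name = ".thin3d_cpp")]]
LogicalVector thin3d_cpp(LogicalVector mask, NumericVector priority,
                         IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<char> obj(n);
  for (R_xlen_t i = 0; i < n; ++i) obj[i] = mask[i] ? 1 : 0;

  auto neighborhood = [&](R_xlen_t idx, bool nb[27]) {
    int z = idx % nz;
    int y = (idx / nz) % ny;
    int x = idx / ((R_xlen_t)nz * ny);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          int zz = z + dz, yy = y + dy, xx = x + dx;
          bool in = zz >= 0 && zz < nz && yy >= 0 && yy < ny && xx >= 0 && xx < nx;
          nb[nbIndex(dz, dy, dx)] =
              in && obj[zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)];
        }
  };

  auto neighborCount = [&](const bool nb[27]) {
    int cnt = 0;
    for (int i = 0; i < 27; ++i)
      if (i != 13 && nb[i]) ++cnt;
    return cnt;
  };

  // border-sequential thinning, 6 directional subiterations per pass so the
  // object erodes uniformly from all sides; candidates within a subiteration
  // are visited in order of increasing distance-to-background priority,
  // which keeps the surviving curve on the medial axis
  const int dirs[6][3] = {{-1, 0, 0}, {1, 0, 0}, {0, -1, 0},
                          {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
  bool nb[27];
  std::vector<std::pair<double, R_xlen_t> > cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      cand.clear();
      const int dz = dirs[dir][0], dy = dirs[dir][1], dx = dirs[dir][2];
      for (R_xlen_t i = 0; i < n; ++i) {
        if (!obj[i]) continue;
        int z = i % nz;
        int y = (i / nz) % ny;
        int x = i / ((R_xlen_t)nz * ny);
        int zz = z + dz, yy = y + dy, xx = x + dx;
        bool bgNb = zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 ||
                    xx >= nx ||
                    !obj[zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)];
        if (bgNb) cand.push_back(std::make_pair(priority[i], i));
      }
      std::sort(cand.begin(), cand.end());
      for (size_t k = 0; k < cand.size(); ++k) {
        R_xlen_t idx = cand[k].second;
        if (!obj[idx]) continue;
        neighborhood(idx, nb);
        int cnt = neighborCount(nb);
        if (cnt <= 1) continue;  // curve endpoint or isolated: preserved
        if (countObjComponents26(nb) != 1) continue;
        if (countBgComponents6(nb) != 1) continue;
        obj[idx] = 0;
        changed = true;
      }
    }
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = obj[i] != 0;
  out.attr("dim") = dims;
  return out;
}
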