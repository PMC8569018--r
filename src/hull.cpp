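#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Incremental 3D convex hull (visible-face deletion over horizon edges) plus
// lattice-point counting inside the hull. Used for solidity: mask voxels /
// hull voxels. Points are voxel coordinates, so exact enough with a small
// tolerance; a degenerate (coplanar) point set is an error.

namespace {

struct Vec3 {
  double x, y, z;
};
inline Vec3 sub(const Vec3& a, const Vec3& b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }

struct Face {
  int a, b, c;
  Vec3 n;       // outward unit normal
  double off;   // n . p = off on the face plane
  bool alive;
};

}  // namespace

// pts: n x 3 matrix of (z, y, x) voxel coordinates (any consistent order).
// Returns hull volume, number of facets, lattice-point count inside the hull.
// [[Rcpp::export(name = ".hull3d_cpp")]]
List hull3d_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("degenerate mask: fewer than 4 hull candidate points");
  std::vector<Vec3> P(n);
  double scale = 1.0;
  for (int i = 0; i < n; ++i) {
    P[i] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    scale = std::max(scale, std::max(std::fabs(P[i].x),
                     std::max(std::fabs(P[i].y), std::fabs(P[i].z))));
  }
  const double eps = 1e-9 * scale;

  // initial non-degenerate tetrahedron
  int i1 = 1;
  double best = -1;
  for (int i = 1; i < n; ++i) {
    double d = norm(sub(P[i], P[0]));
    if (d > best) { best = d; i1 = i; }
  }
  if (best < eps) stop("degenerate mask: all points coincide");
  Vec3 e1 = sub(P[i1], P[0]);
  int i2 = -1;
  best = -1;
  for (int i = 0; i < n; ++i) {
    double d = norm(cross(e1, sub(P[i], P[0])));
    if (d > best) { best = d; i2 = i; }
  }
  if (best < eps * norm(e1)) stop("degenerate mask: points are collinear");
  Vec3 nrm0 = cross(e1, sub(P[i2], P[0]));
  int i3 = -1;
  best = -1;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(dot(nrm0, sub(P[i], P[0])));
    if (d > best) { best = d; i3 = i; }
  }
  if (best < eps * norm(nrm0)) stop("degenerate mask: points are coplanar");

  Vec3 interior = {(P[0].x + P[i1].x + P[i2].x + P[i3].x) / 4.0,
                   (P[0].y + P[i1].y + P[i2].y + P[i3].y) / 4.0,
                   (P[0].z + P[i1].z + P[i2].z + P[i3].z) / 4.0};

  std::vector<Face> faces;
  auto addFace = [&](int a, int b, int c) {
    Face f;
    f.a = a; f.b = b; f.c = c;
    Vec3 nn = cross(sub(P[b], P[a]), sub(P[c], P[a]));
    double nl = norm(nn);
    if (nl < 1e-14) return;  // degenerate sliver
    nn = {nn.x / nl, nn.y / nl, nn.z / nl};
    double o = dot(nn, P[a]);
    if (dot(nn, interior) > o) {  // flip outward
      nn = {-nn.x, -nn.y, -nn.z};
      o = -o;
      std::swap(f.b, f.c);
    }
    f.n = nn;
    f.off = o;
    f.alive = true;
    faces.push_back(f);
  };
  addFace(0, i1, i2);
  addFace(0, i1, i3);
  addFace(0, i2, i3);
  addFace(i1, i2, i3);

  for (int p = 0; p < n; ++p) {
    if (p == 0 || p == i1 || p == i2 || p == i3) continue;
    std::vector<int> visible;
    for (size_t f = 0; f < faces.size(); ++f)
      if (faces[f].alive && dot(faces[f].n, P[p]) - faces[f].off > eps)
        visible.push_back((int)f);
    if (visible.empty()) continue;
    // horizon = edges appearing exactly once among visible faces
    std::vector<std::pair<int, int> > edges;
    for (int fi : visible) {
      const Face& f = faces[fi];
      int e[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (auto& ed : e) {
        int u = std::min(ed[0], ed[1]), v = std::max(ed[0], ed[1]);
        bool dup = false;
        for (size_t k = 0; k < edges.size(); ++k)
          if (edges[k].first == u && edges[k].second == v) {
            edges.erase(edges.begin() + k);
            dup = true;
            break;
          }
        if (!dup) edges.push_back(std::make_pair(u, v));
      }
    }
    for (int fi : visible) faces[fi].alive = false;
    for (auto& ed : edges) addFace(ed.first, ed.second, p);
  }

  // collect facets, hull volume via signed tetrahedra from the interior point
  std::vector<int> keep;
  double vol = 0.0;
  for (size_t f = 0; f < faces.size(); ++f) {
    if (!faces[f].alive) continue;
    keep.push_back((int)f);
    const Face& fc = faces[f];
    Vec3 a = sub(P[fc.a], interior), b = sub(P[fc.b], interior),
         c = sub(P[fc.c], interior);
    vol += std::fabs(dot(a, cross(b, c))) / 6.0;
  }

  // lattice points inside: per (dim2, dim3) column, intersect half-spaces in dim1
  double lo1 = std::numeric_limits<double>::infinity(), hi1 = -lo1;
  double lo2 = lo1, hi2 = -lo1, lo3 = lo1, hi3 = -lo1;
  for (int i = 0; i < n; ++i) {
    lo1 = std::min(lo1, P[i].x); hi1 = std::max(hi1, P[i].x);
    lo2 = std::min(lo2, P[i].y); hi2 = std::max(hi2, P[i].y);
    lo3 = std::min(lo3, P[i].z); hi3 = std::max(hi3, P[i].z);
  }
  const double tol = 1e-7 * scale;
  long long count = 0;
  for (int y = (int)std::ceil(lo2 - tol); y <= (int)std::floor(hi2 + tol); ++y) {
    for (int z = (int)std::ceil(lo3 - tol); z <= (int)std::floor(hi3 + tol); ++z) {
      double a = lo1 - tol, b = hi1 + tol;
      bool feasible = true;
      for (int fi : keep) {
        const Face& f = faces[fi];
        double rhs = f.off - f.n.y * y - f.n.z * z;
        if (std::fabs(f.n.x) < 1e-12) {
          if (rhs < -tol) { feasible = false; break; }
        } else if (f.n.x > 0) {
          b = std::min(b, (rhs + tol) / f.n.x);
        } else {
          a = std::max(a, (rhs + tol) / f.n.x);  // dividing by n.x < 0 flips
        }
        if (a > b) { feasible = false; break; }
      }
      if (!feasible) continue;
      long long zlo = (long long)std::ceil(a - 1e-9);
      long long zhi = (long long)std::floor(b + 1e-9);
      if (zhi >= zlo) count += (zhi - zlo + 1);
    }
  }

  return List::create(_["volume"] = vol, _["nfaces"] = (int)keep.size(),
                      _["count"] = (double)count);
}
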