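#include <Rcpp.h>
#include <vector>
#include <map>
#include <utility>
#include <cmath>

using namespace Rcpp;

// Incremental 3D convex hull over a point cloud. Faces are kept outward
// oriented with respect to an interior reference point; a point is inserted by
// deleting the faces it can see and stitching new faces along the horizon.
// O(n * F) scans are acceptable at the mesh sizes used here (<= ~2e4 points).

namespace {

struct Face {
  int a, b, c;
  double nx, ny, nz, off;  // outward normal and plane offset (n . x = off)
  bool alive;
};

inline void face_plane(const std::vector<double>& X, const std::vector<double>& Y,
                       const std::vector<double>& Z, Face& f) {
  const double ux = X[f.b] - X[f.a], uy = Y[f.b] - Y[f.a], uz = Z[f.b] - Z[f.a];
  const double vx = X[f.c] - X[f.a], vy = Y[f.c] - Y[f.a], vz = Z[f.c] - Z[f.a];
  f.nx = uy * vz - uz * vy;
  f.ny = uz * vx - ux * vz;
  f.nz = ux * vy - uy * vx;
  f.off = f.nx * X[f.a] + f.ny * Y[f.a] + f.nz * Z[f.a];
}

inline double signed_dist(const std::vector<double>& X, const std::vector<double>& Y,
                          const std::vector<double>& Z, const Face& f, int p) {
  return f.nx * X[p] + f.ny * Y[p] + f.nz * Z[p] - f.off;
}

}  // namespace

// [[Rcpp::export(name = ".hull3d_cpp")]]
List hull3d_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("convex hull needs at least 4 points");
  std::vector<double> X(n), Y(n), Z(n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    X[i] = pts(i, 0); Y[i] = pts(i, 1); Z[i] = pts(i, 2);
    scale = std::max(scale, std::max(std::fabs(X[i]),
            std::max(std::fabs(Y[i]), std::fabs(Z[i]))));
  }
  if (scale == 0.0) scale = 1.0;
  const double eps = 1e-10 * scale * scale;  // distances carry |n| ~ scale^2

  // initial simplex: extremes in x, then farthest from line, then from plane
  int i0 = 0, i1 = 0;
  for (int i = 1; i < n; ++i) {
    if (X[i] < X[i0]) i0 = i;
    if (X[i] > X[i1]) i1 = i;
  }
  if (i0 == i1) { i1 = (i0 + 1) % n; }
  int i2 = -1; double best = eps;
  for (int i = 0; i < n; ++i) {
    const double ax = X[i1] - X[i0], ay = Y[i1] - Y[i0], az = Z[i1] - Z[i0];
    const double bx = X[i] - X[i0], by = Y[i] - Y[i0], bz = Z[i] - Z[i0];
    const double cx = ay * bz - az * by, cy = az * bx - ax * bz, cz = ax * by - ay * bx;
    const double d2 = cx * cx + cy * cy + cz * cz;
    if (d2 > best) { best = d2; i2 = i; }
  }
  if (i2 < 0) stop("degenerate point set: all points collinear");
  Face base{ i0, i1, i2, 0, 0, 0, 0, true };
  std::vector<double> XX = X;  // alias clarity only
  face_plane(X, Y, Z, base);
  int i3 = -1; best = eps;
  for (int i = 0; i < n; ++i) {
    const double d = std::fabs(signed_dist(X, Y, Z, base, i));
    if (d > best) { best = d; i3 = i; }
  }
  if (i3 < 0) stop("degenerate point set: all points coplanar");

  const double cx = (X[i0] + X[i1] + X[i2] + X[i3]) / 4.0;
  const double cy = (Y[i0] + Y[i1] + Y[i2] + Y[i3]) / 4.0;
  const double cz = (Z[i0] + Z[i1] + Z[i2] + Z[i3]) / 4.0;

  std::vector<Face> faces;
  faces.reserve(8 * static_cast<size_t>(std::sqrt(static_cast<double>(n))) + 64);
  int tet[4][3] = { {i0, i1, i2}, {i0, i1, i3}, {i0, i2, i3}, {i1, i2, i3} };
  for (auto& t : tet) {
    Face f{ t[0], t[1], t[2], 0, 0, 0, 0, true };
    face_plane(X, Y, Z, f);
    if (f.nx * cx + f.ny * cy + f.nz * cz - f.off > 0) {  // flip to face outward
      std::swap(f.b, f.c);
      face_plane(X, Y, Z, f);
    }
    faces.push_back(f);
  }

  std::vector<int> visible;
  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    visible.clear();
    for (size_t fi = 0; fi < faces.size(); ++fi) {
      if (faces[fi].alive && signed_dist(X, Y, Z, faces[fi], p) > eps)
        visible.push_back(static_cast<int>(fi));
    }
    if (visible.empty()) continue;
    // horizon = directed edges of visible faces whose reverse is not visible
    std::map<std::pair<int,int>, int> edges;
    for (int fi : visible) {
      const Face& f = faces[fi];
      edges[{f.a, f.b}] = 1; edges[{f.b, f.c}] = 1; edges[{f.c, f.a}] = 1;
    }
    for (int fi : visible) faces[fi].alive = false;
    for (const auto& e : edges) {
      if (edges.count({e.first.second, e.first.first})) continue;  // interior
      Face f{ e.first.first, e.first.second, p, 0, 0, 0, 0, true };
      face_plane(X, Y, Z, f);
      if (f.nx * cx + f.ny * cy + f.nz * cz - f.off > 0) {
        std::swap(f.b, f.c);
        face_plane(X, Y, Z, f);
      }
      faces.push_back(f);
    }
  }

  double area = 0.0, vol = 0.0;
  int nf = 0;
  for (const Face& f : faces) {
    if (!f.alive) continue;
    ++nf;
    const double nrm = std::sqrt(f.nx * f.nx + f.ny * f.ny + f.nz * f.nz);
    area += 0.5 * nrm;
    vol += ((X[f.a] - cx) * ((Y[f.b] - cy) * (Z[f.c] - cz) - (Z[f.b] - cz) * (Y[f.c] - cy))
          + (Y[f.a] - cy) * ((Z[f.b] - cz) * (X[f.c] - cx) - (X[f.b] - cx) * (Z[f.c] - cz))
          + (Z[f.a] - cz) * ((X[f.b] - cx) * (Y[f.c] - cy) - (Y[f.b] - cy) * (X[f.c] - cx))) / 6.0;
  }
  IntegerMatrix F(nf, 3);
  int r = 0;
  for (const Face& f : faces) {
    if (!f.alive) continue;
    F(r, 0) = f.a + 1; F(r, 1) = f.b + 1; F(r, 2) = f.c + 1;
    ++r;
  }
  (void)XX;
  return List::create(_["area"] = area, _["volume"] = vol, _["faces"] = F);
}
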