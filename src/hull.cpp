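// 3-D convex hull by beneath-beyond incremental insertion, used for the
// gyrification-index denominator.  For large point clouds the candidate set
// is first reduced to support points (argmax of the dot product over a
// Fibonacci-sphere set of directions); every true hull vertex is the support
// point of some direction, so with a dense direction set the hull area of
// the reduced cloud matches the full hull area to well below the mesh
// discretisation error of the numerator.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

struct Face {
  int a, b, c;        // indices into the candidate point list
  double nx, ny, nz;  // outward normal (not normalised)
  double off;         // plane offset: n . x = off
  bool alive;
};

static inline void face_plane(Face &f, const std::vector<double> &px,
                              const std::vector<double> &py,
                              const std::vector<double> &pz) {
  double ux = px[f.b] - px[f.a], uy = py[f.b] - py[f.a], uz = pz[f.b] - pz[f.a];
  double vx = px[f.c] - px[f.a], vy = py[f.c] - py[f.a], vz = pz[f.c] - pz[f.a];
  f.nx = uy * vz - uz * vy;
  f.ny = uz * vx - ux * vz;
  f.nz = ux * vy - uy * vx;
  f.off = f.nx * px[f.a] + f.ny * py[f.a] + f.nz * pz[f.a];
}

// [[Rcpp::export]]
List cpp_convex_hull(NumericMatrix P, int max_candidates) {
  const int n = P.nrow();
  if (n < 4) stop("convex hull needs at least 4 points");

  // --- candidate reduction by support sampling -----------------------------
  std::vector<int> cand;
  if (n <= max_candidates) {
    cand.resize(n);
    for (int i = 0; i < n; ++i) cand[i] = i;
  } else {
    int K = max_candidates;
    std::vector<char> taken(n, 0);
    const double ga = M_PI * (3.0 - std::sqrt(5.0));  // golden angle
    for (int k = 0; k < K; ++k) {
      double zc = 1.0 - 2.0 * (k + 0.5) / K;
      double r = std::sqrt(std::max(0.0, 1.0 - zc * zc));
      double th = ga * k;
      double dx = r * std::cos(th), dy = r * std::sin(th), dz = zc;
      int best = 0;
      double bv = -1e300;
      for (int i = 0; i < n; ++i) {
        double v = dx * P(i, 0) + dy * P(i, 1) + dz * P(i, 2);
        if (v > bv) { bv = v; best = i; }
      }
      if (!taken[best]) { taken[best] = 1; cand.push_back(best); }
    }
  }

  const int m = (int)cand.size();
  if (m < 4) stop("degenerate input: fewer than 4 distinct support points");
  std::vector<double> px(m), py(m), pz(m);
  for (int i = 0; i < m; ++i) {
    px[i] = P(cand[i], 0); py[i] = P(cand[i], 1); pz[i] = P(cand[i], 2);
  }

  // scale-aware tolerance
  double scale = 0;
  for (int i = 0; i < m; ++i)
    scale = std::max(scale, std::fabs(px[i]) + std::fabs(py[i]) + std::fabs(pz[i]));
  const double eps = 1e-9 * std::max(scale, 1.0);

  // --- initial tetrahedron -------------------------------------------------
  int i0 = 0, i1 = -1;
  double best = -1;
  for (int i = 0; i < m; ++i)      // farthest pair from point 0 (adequate seed)
    if (px[i] < px[i0]) i0 = i;
  for (int i = 0; i < m; ++i) {
    double d = (px[i]-px[i0])*(px[i]-px[i0]) + (py[i]-py[i0])*(py[i]-py[i0]) +
               (pz[i]-pz[i0])*(pz[i]-pz[i0]);
    if (d > best) { best = d; i1 = i; }
  }
  if (best < eps * eps) stop("degenerate input: all points coincide");
  int i2 = -1; best = -1;
  double ex = px[i1]-px[i0], ey = py[i1]-py[i0], ez = pz[i1]-pz[i0];
  for (int i = 0; i < m; ++i) {
    double wx = px[i]-px[i0], wy = py[i]-py[i0], wz = pz[i]-pz[i0];
    double cx = ey*wz - ez*wy, cy = ez*wx - ex*wz, cz = ex*wy - ey*wx;
    double d = cx*cx + cy*cy + cz*cz;
    if (d > best) { best = d; i2 = i; }
  }
  if (best < eps * eps) stop("degenerate input: points are collinear");
  int i3 = -1; best = -1;
  Face base{ i0, i1, i2, 0, 0, 0, 0, true };
  face_plane(base, px, py, pz);
  for (int i = 0; i < m; ++i) {
    double d = std::fabs(base.nx*px[i] + base.ny*py[i] + base.nz*pz[i] - base.off);
    if (d > best) { best = d; i3 = i; }
  }
  if (best < eps) stop("degenerate input: points are coplanar");

  std::vector<Face> faces;
  double cx0 = (px[i0]+px[i1]+px[i2]+px[i3]) / 4.0;
  double cy0 = (py[i0]+py[i1]+py[i2]+py[i3]) / 4.0;
  double cz0 = (pz[i0]+pz[i1]+pz[i2]+pz[i3]) / 4.0;
  int tet[4][3] = {{i0,i1,i2},{i0,i1,i3},{i0,i2,i3},{i1,i2,i3}};
  for (auto &t : tet) {
    Face f{ t[0], t[1], t[2], 0, 0, 0, 0, true };
    face_plane(f, px, py, pz);
    if (f.nx*cx0 + f.ny*cy0 + f.nz*cz0 - f.off > 0) {  // centroid must be inside
      std::swap(f.b, f.c);
      face_plane(f, px, py, pz);
    }
    faces.push_back(f);
  }

  // --- incremental insertion ----------------------------------------------
  std::vector<char> used(m, 0);
  used[i0] = used[i1] = used[i2] = used[i3] = 1;
  for (int q = 0; q < m; ++q) {
    if (used[q]) continue;
    used[q] = 1;
    std::vector<int> visible;
    for (int f = 0; f < (int)faces.size(); ++f) {
      if (!faces[f].alive) continue;
      if (faces[f].nx*px[q] + faces[f].ny*py[q] + faces[f].nz*pz[q] -
          faces[f].off > eps)
        visible.push_back(f);
    }
    if (visible.empty()) continue;  // inside current hull
    // boundary = directed edges of visible faces whose reverse is not visible
    std::unordered_map<uint64_t, int> dir;
    for (int f : visible) {
      int v[3] = {faces[f].a, faces[f].b, faces[f].c};
      for (int e = 0; e < 3; ++e) {
        uint64_t a = (uint64_t)v[e], b = (uint64_t)v[(e+1)%3];
        dir[(a << 32) | b] += 1;
      }
      faces[f].alive = false;
    }
    for (auto &kv : dir) {
      uint64_t a = kv.first >> 32, b = kv.first & 0xffffffffULL;
      if (dir.count((b << 32) | a)) continue;  // interior edge of the hole
      Face f{ (int)a, (int)b, q, 0, 0, 0, 0, true };
      face_plane(f, px, py, pz);
      faces.push_back(f);
    }
  }

  // --- collect live faces, area, volume ------------------------------------
  int nf = 0;
  for (auto &f : faces) if (f.alive) ++nf;
  IntegerMatrix Fo(nf, 3);
  double area = 0, vol = 0;
  int r = 0;
  for (auto &f : faces) {
    if (!f.alive) continue;
    Fo(r, 0) = cand[f.a] + 1; Fo(r, 1) = cand[f.b] + 1; Fo(r, 2) = cand[f.c] + 1;
    double nn = std::sqrt(f.nx*f.nx + f.ny*f.ny + f.nz*f.nz);
    area += 0.5 * nn;
    vol += (px[f.a] * (py[f.b]*pz[f.c] - pz[f.b]*py[f.c])
          - py[f.a] * (px[f.b]*pz[f.c] - pz[f.b]*px[f.c])
          + pz[f.a] * (px[f.b]*py[f.c] - py[f.b]*px[f.c])) / 6.0;
    ++r;
  }
  return List::create(_["faces"] = Fo, _["area"] = area,
                      _["volume"] = std::fabs(vol));
}
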