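// Voxel-grid and triangle-mesh primitives used by the morphometry layer:
// iso-surface extraction by marching tetrahedra on a Kuhn-subdivided grid,
// 6-connected component labelling, separable Gaussian smoothing of a scalar
// field, uniform Laplacian mesh smoothing, and discrete mean curvature via
// the cotangent Laplacian.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Iso-surface extraction
// ---------------------------------------------------------------------------

// The unit cube is split into the six Kuhn tetrahedra that share the main
// diagonal (0,0,0)-(1,1,1); the subdivision is identical in every cell, so
// shared cube faces are triangulated compatibly and the extracted surface is
// watertight by construction.  Each tetrahedron is the vertex chain
// c0 -> c0+e_{p0} -> c0+e_{p0}+e_{p1} -> (1,1,1) for a permutation p of xyz.
static const int kPerm[6][3] = {
  {0, 1, 2}, {0, 2, 1}, {1, 0, 2}, {1, 2, 0}, {2, 0, 1}, {2, 1, 0}
};

struct MeshAccum {
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;              // 0-based vertex indices
  std::unordered_map<uint64_t, int> edge_vertex;
};

static inline uint64_t edge_key(uint64_t a, uint64_t b) {
  if (a > b) std::swap(a, b);
  return (a << 32) | b;
}

// vertex on the segment between grid nodes ga and gb, by linear interpolation
// of the field; t clamped away from 0/1 so no mesh vertex coincides with a
// grid node (keeps faces non-degenerate while preserving shared-edge keys)
static int edge_point(MeshAccum &m, uint64_t ga, uint64_t gb,
                      const double *ca, const double *cb,
                      double va, double vb, double level,
                      const double *spacing, const double *origin) {
  uint64_t key = edge_key(ga, gb);
  auto it = m.edge_vertex.find(key);
  if (it != m.edge_vertex.end()) return it->second;
  // clamping away from the segment ends keeps triangles well conditioned
  // (no slivers); the vertex displacement is at most 0.05 voxel
  double t = (vb == va) ? 0.5 : (level - va) / (vb - va);
  if (t < 0.05) t = 0.05;
  if (t > 0.95) t = 0.95;
  if (ga > gb) t = 1.0 - t;                // canonical direction for the key
  const double *lo = (ga <= gb) ? ca : cb;
  const double *hi = (ga <= gb) ? cb : ca;
  int id = (int)m.vx.size();
  m.vx.push_back(origin[0] + spacing[0] * (lo[0] + t * (hi[0] - lo[0])));
  m.vy.push_back(origin[1] + spacing[1] * (lo[1] + t * (hi[1] - lo[1])));
  m.vz.push_back(origin[2] + spacing[2] * (lo[2] + t * (hi[2] - lo[2])));
  m.edge_vertex.emplace(key, id);
  return id;
}

static inline void emit_triangle(MeshAccum &m, int a, int b, int c,
                                 const double inside_pt[3]) {
  // orient so the face normal points away from the inside of the region
  double ax = m.vx[a], ay = m.vy[a], az = m.vz[a];
  double ux = m.vx[b] - ax, uy = m.vy[b] - ay, uz = m.vz[b] - az;
  double wx = m.vx[c] - ax, wy = m.vy[c] - ay, wz = m.vz[c] - az;
  double nx = uy * wz - uz * wy;
  double ny = uz * wx - ux * wz;
  double nz = ux * wy - uy * wx;
  double cx = (ax + m.vx[b] + m.vx[c]) / 3.0;
  double cy = (ay + m.vy[b] + m.vy[c]) / 3.0;
  double cz = (az + m.vz[b] + m.vz[c]) / 3.0;
  double dot = nx * (inside_pt[0] - cx) + ny * (inside_pt[1] - cy) +
               nz * (inside_pt[2] - cz);
  if (dot > 0) std::swap(b, c);
  m.f0.push_back(a); m.f1.push_back(b); m.f2.push_back(c);
}

// [[Rcpp::export]]
List cpp_isosurface(NumericVector field, IntegerVector dim,
                    NumericVector spacing, NumericVector origin,
                    double level) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sp[3] = {spacing[0], spacing[1], spacing[2]};
  const double org[3] = {origin[0], origin[1], origin[2]};
  const double *F = field.begin();
  MeshAccum m;

  double corner[8][3];  // voxel-grid (index) coordinates of cell corners
  uint64_t gidx[8];
  double val[8];

  for (int k = 0; k < nz - 1; ++k) {
    for (int j = 0; j < ny - 1; ++j) {
      for (int i = 0; i < nx - 1; ++i) {
        // quick reject on the cell's 8 corners
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int di = c & 1, dj = (c >> 1) & 1, dk = (c >> 2) & 1;
          int ii = i + di, jj = j + dj, kk = k + dk;
          uint64_t g = (uint64_t)ii + (uint64_t)nx * (jj + (uint64_t)ny * kk);
          gidx[c] = g;
          val[c] = F[g];
          corner[c][0] = ii; corner[c][1] = jj; corner[c][2] = kk;
          if (val[c] > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;

        for (int t = 0; t < 6; ++t) {
          // tetrahedron corners as cube-corner codes along the Kuhn chain
          int code[4];
          code[0] = 0;
          code[1] = code[0] | (1 << kPerm[t][0]);
          code[2] = code[1] | (1 << kPerm[t][1]);
          code[3] = 7;
          int ins[4], nin = 0, outs[4], nout = 0;
          for (int v = 0; v < 4; ++v) {
            if (val[code[v]] > level) ins[nin++] = code[v];
            else outs[nout++] = code[v];
          }
          if (nin == 0 || nin == 4) continue;
          double inside_pt[3];
          for (int d = 0; d < 3; ++d) {
            double s = 0;
            for (int v = 0; v < nin; ++v)
              s += org[d] + sp[d] * corner[ins[v]][d];
            inside_pt[d] = s / nin;
          }
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? ins[0] : outs[0];
            int others[3], no = 0;
            for (int v = 0; v < 4; ++v)
              if (code[v] != apex) others[no++] = code[v];
            int p[3];
            for (int v = 0; v < 3; ++v)
              p[v] = edge_point(m, gidx[apex], gidx[others[v]],
                                corner[apex], corner[others[v]],
                                val[apex], val[others[v]], level, sp, org);
            emit_triangle(m, p[0], p[1], p[2], inside_pt);
          } else {  // nin == 2: quad strip -> two triangles
            int a = ins[0], b = ins[1], c = outs[0], d = outs[1];
            int pac = edge_point(m, gidx[a], gidx[c], corner[a], corner[c],
                                 val[a], val[c], level, sp, org);
            int pad = edge_point(m, gidx[a], gidx[d], corner[a], corner[d],
                                 val[a], val[d], level, sp, org);
            int pbd = edge_point(m, gidx[b], gidx[d], corner[b], corner[d],
                                 val[b], val[d], level, sp, org);
            int pbc = edge_point(m, gidx[b], gidx[c], corner[b], corner[c],
                                 val[b], val[c], level, sp, org);
            emit_triangle(m, pac, pad, pbd, inside_pt);
            emit_triangle(m, pac, pbd, pbc, inside_pt);
          }
        }
      }
    }
  }

  int nv = (int)m.vx.size(), nf = (int)m.f0.size();
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = m.vx[v]; V(v, 1) = m.vy[v]; V(v, 2) = m.vz[v];
  }
  IntegerMatrix Fc(nf, 3);
  for (int f = 0; f < nf; ++f) {
    Fc(f, 0) = m.f0[f] + 1; Fc(f, 1) = m.f1[f] + 1; Fc(f, 2) = m.f2[f] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = Fc);
}

// ---------------------------------------------------------------------------
// 6-connected component labelling of a binary volume
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    stack.clear();
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i = cur % nx, j = (cur / nx) % ny, k = cur / ((R_xlen_t)nx * ny);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int q = 0; q < 6; ++q) {
        int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t nb = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[nb] && lab[nb] == 0) {
          lab[nb] = next;
          stack.push_back(nb);
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing (replicate padding), sigma in voxels per axis
// ---------------------------------------------------------------------------

static void smooth_axis(std::vector<double> &a, int nx, int ny, int nz,
                        int axis, double sigma) {
  if (sigma <= 0) return;
  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * rad + 1);
  double s = 0;
  for (int u = -rad; u <= rad; ++u) {
    ker[u + rad] = std::exp(-0.5 * u * u / (sigma * sigma));
    s += ker[u + rad];
  }
  for (double &kv : ker) kv /= s;
  int n[3] = {nx, ny, nz};
  R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  int len = n[axis];
  R_xlen_t st = stride[axis];
  std::vector<double> line(len);
  int oa = (axis + 1) % 3, ob = (axis + 2) % 3;
  for (int b = 0; b < n[ob]; ++b) {
    for (int aidx = 0; aidx < n[oa]; ++aidx) {
      R_xlen_t base = (R_xlen_t)aidx * stride[oa] + (R_xlen_t)b * stride[ob];
      for (int u = 0; u < len; ++u) line[u] = a[base + (R_xlen_t)u * st];
      for (int u = 0; u < len; ++u) {
        double acc = 0;
        for (int w = -rad; w <= rad; ++w) {
          int v = u + w;
          if (v < 0) v = 0;
          if (v >= len) v = len - 1;
          acc += ker[w + rad] * line[v];
        }
        a[base + (R_xlen_t)u * st] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector arr, IntegerVector dim,
                                  NumericVector sigma_vox) {
  std::vector<double> a(arr.begin(), arr.end());
  for (int axis = 0; axis < 3; ++axis)
    smooth_axis(a, dim[0], dim[1], dim[2], axis, sigma_vox[axis]);
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Mesh operations
// ---------------------------------------------------------------------------

static std::vector<std::vector<int>> vertex_adjacency(const IntegerMatrix &F,
                                                      int nv) {
  std::vector<std::vector<int>> adj(nv);
  auto add = [&](int a, int b) {
    adj[a].push_back(b);
    adj[b].push_back(a);
  };
  for (int f = 0; f < F.nrow(); ++f) {
    int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    add(a, b); add(b, c); add(c, a);
  }
  for (auto &v : adj) {
    std::sort(v.begin(), v.end());
    v.erase(std::unique(v.begin(), v.end()), v.end());
  }
  return adj;
}

// [[Rcpp::export]]
NumericMatrix cpp_smooth_mesh(NumericMatrix V, IntegerMatrix F,
                              int iterations, double lambda) {
  int nv = V.nrow();
  auto adj = vertex_adjacency(F, nv);
  std::vector<double> x(nv), y(nv), z(nv);
  for (int v = 0; v < nv; ++v) { x[v] = V(v,0); y[v] = V(v,1); z[v] = V(v,2); }
  std::vector<double> nx2(nv), ny2(nv), nz2(nv);
  for (int it = 0; it < iterations; ++it) {
    for (int v = 0; v < nv; ++v) {
      if (adj[v].empty()) { nx2[v]=x[v]; ny2[v]=y[v]; nz2[v]=z[v]; continue; }
      double mx = 0, my = 0, mz = 0;
      for (int u : adj[v]) { mx += x[u]; my += y[u]; mz += z[u]; }
      double k = 1.0 / adj[v].size();
      nx2[v] = x[v] + lambda * (mx * k - x[v]);
      ny2[v] = y[v] + lambda * (my * k - y[v]);
      nz2[v] = z[v] + lambda * (mz * k - z[v]);
    }
    x.swap(nx2); y.swap(ny2); z.swap(nz2);
  }
  NumericMatrix out(nv, 3);
  for (int v = 0; v < nv; ++v) { out(v,0)=x[v]; out(v,1)=y[v]; out(v,2)=z[v]; }
  return out;
}

// Discrete mean curvature magnitude per vertex (cotangent Laplacian,
// Meyer et al. mixed-area simplified to barycentric area).  Returns |H| and
// the per-vertex area weight.
// [[Rcpp::export]]
List cpp_mean_curvature(NumericMatrix V, IntegerMatrix F) {
  int nv = V.nrow(), nf = F.nrow();
  std::vector<double> Kx(nv, 0), Ky(nv, 0), Kz(nv, 0), A(nv, 0),
    Nx(nv, 0), Ny(nv, 0), Nz(nv, 0);
  for (int f = 0; f < nf; ++f) {
    int id[3] = {F(f,0) - 1, F(f,1) - 1, F(f,2) - 1};
    double p[3][3];
    for (int v = 0; v < 3; ++v)
      for (int d = 0; d < 3; ++d) p[v][d] = V(id[v], d);
    // face area
    double e1[3], e2[3], cr[3];
    for (int d = 0; d < 3; ++d) { e1[d] = p[1][d]-p[0][d]; e2[d] = p[2][d]-p[0][d]; }
    cr[0] = e1[1]*e2[2]-e1[2]*e2[1];
    cr[1] = e1[2]*e2[0]-e1[0]*e2[2];
    cr[2] = e1[0]*e2[1]-e1[1]*e2[0];
    double area = 0.5 * std::sqrt(cr[0]*cr[0]+cr[1]*cr[1]+cr[2]*cr[2]);
    if (area <= 0) continue;
    for (int v = 0; v < 3; ++v) {
      A[id[v]] += area / 3.0;
      // oriented face normal accumulates into the vertex normal
      Nx[id[v]] += cr[0]; Ny[id[v]] += cr[1]; Nz[id[v]] += cr[2];
    }
    // cot of the angle at vertex v weights the opposite edge (u, w)
    for (int v = 0; v < 3; ++v) {
      int u = (v + 1) % 3, w = (v + 2) % 3;
      double a[3], b[3];
      double dot = 0;
      for (int d = 0; d < 3; ++d) {
        a[d] = p[u][d] - p[v][d];
        b[d] = p[w][d] - p[v][d];
        dot += a[d] * b[d];
      }
      double cx = a[1]*b[2]-a[2]*b[1];
      double cy = a[2]*b[0]-a[0]*b[2];
      double cz = a[0]*b[1]-a[1]*b[0];
      double crn = std::sqrt(cx*cx + cy*cy + cz*cz);
      if (crn < 1e-12) continue;
      double cot = dot / crn;
      for (int d = 0; d < 3; ++d) {
        double diff_u = p[u][d] - p[w][d];
        // edge (u, w): K_u += cot * (x_u - x_w); K_w += cot * (x_w - x_u)
        double val = cot * diff_u;
        if (d == 0) { Kx[id[u]] += val; Kx[id[w]] -= val; }
        else if (d == 1) { Ky[id[u]] += val; Ky[id[w]] -= val; }
        else { Kz[id[u]] += val; Kz[id[w]] -= val; }
      }
    }
  }
  NumericVector H(nv), Aout(nv);
  for (int v = 0; v < nv; ++v) {
    double norm = std::sqrt(Kx[v]*Kx[v] + Ky[v]*Ky[v] + Kz[v]*Kz[v]);
    // sign from the outward vertex normal: positive where the surface is
    // locally convex (sphere convention H = 1/r > 0)
    double dot = Kx[v]*Nx[v] + Ky[v]*Ny[v] + Kz[v]*Nz[v];
    double sgn = (dot >= 0) ? 1.0 : -1.0;
    H[v] = (A[v] > 0) ? sgn * norm / (4.0 * A[v]) : 0.0;
    Aout[v] = A[v];
  }
  return List::create(_["H"] = H, _["area"] = Aout);
}

// Counts of directed and undirected edge multiplicities: a closed,
// consistently oriented 2-manifold has every directed edge exactly once and
// every undirected edge exactly twice.
// [[Rcpp::export]]
List cpp_edge_counts(IntegerMatrix F) {
  std::unordered_map<uint64_t, int> dir, undir;
  for (int f = 0; f < F.nrow(); ++f) {
    int v[3] = {F(f,0), F(f,1), F(f,2)};
    for (int e = 0; e < 3; ++e) {
      uint64_t a = (uint64_t)v[e], b = (uint64_t)v[(e + 1) % 3];
      dir[(a << 32) | b] += 1;
      undir[edge_key(a, b)] += 1;
    }
  }
  int max_dir = 0, max_und = 0, min_und = 1000000;
  for (auto &kv : dir) max_dir = std::max(max_dir, kv.second);
  for (auto &kv : undir) {
    max_und = std::max(max_und, kv.second);
    min_und = std::min(min_und, kv.second);
  }
  return List::create(_["max_directed"] = max_dir,
                      _["max_undirected"] = max_und,
                      _["min_undirected"] = undir.empty() ? 0 : min_und,
                      _["n_edges"] = (int)undir.size());
}
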