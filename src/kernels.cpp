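// Compiled kernels: conservative triangle rasterization (13-axis SAT),
// per-slice flood filling, isosurface extraction on uniform grids,
// triangle-triangle intersection search, and point/mesh queries.
// Grids are column-major (x fastest) to match R array layout.
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------- small vec ops
static inline void vsub(const double a[3], const double b[3], double r[3]) {
  r[0] = a[0] - b[0]; r[1] = a[1] - b[1]; r[2] = a[2] - b[2];
}
static inline void vcross(const double a[3], const double b[3], double r[3]) {
  r[0] = a[1] * b[2] - a[2] * b[1];
  r[1] = a[2] * b[0] - a[0] * b[2];
  r[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double vdot(const double a[3], const double b[3]) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// ------------------------------------------------- triangle/box SAT (13 axes)
// Akenine-Moller style test on a box centred at origin with half-sizes hs.
// Touching counts as overlap (comparisons are <= / >=).
static bool planeBoxOverlap(const double n[3], const double v[3], const double hs[3]) {
  double vmin[3], vmax[3];
  for (int q = 0; q < 3; q++) {
    if (n[q] > 0.0) { vmin[q] = -hs[q] - v[q]; vmax[q] =  hs[q] - v[q]; }
    else            { vmin[q] =  hs[q] - v[q]; vmax[q] = -hs[q] - v[q]; }
  }
  if (vdot(n, vmin) > 0.0) return false;
  if (vdot(n, vmax) >= 0.0) return true;
  return false;
}

static bool triBoxOverlap(const double c[3], const double hs[3],
                          const double t0[3], const double t1[3], const double t2[3]) {
  double v[3][3], e[3][3];
  vsub(t0, c, v[0]); vsub(t1, c, v[1]); vsub(t2, c, v[2]);
  vsub(v[1], v[0], e[0]); vsub(v[2], v[1], e[1]); vsub(v[0], v[2], e[2]);

  // box axes
  for (int q = 0; q < 3; q++) {
    double mn = std::min(v[0][q], std::min(v[1][q], v[2][q]));
    double mx = std::max(v[0][q], std::max(v[1][q], v[2][q]));
    if (mn > hs[q] || mx < -hs[q]) return false;
  }
  // 9 edge cross-product axes: cross(unit axis a, edge k)
  for (int k = 0; k < 3; k++)
    for (int a = 0; a < 3; a++) {
      double ax[3] = { 0, 0, 0 };
      int i = (a + 1) % 3, j = (a + 2) % 3;
      ax[i] = -e[k][j];
      ax[j] =  e[k][i];
      double p0 = vdot(ax, v[0]), p1 = vdot(ax, v[1]), p2 = vdot(ax, v[2]);
      double mn = std::min(p0, std::min(p1, p2));
      double mx = std::max(p0, std::max(p1, p2));
      double rad = hs[0] * std::fabs(ax[0]) + hs[1] * std::fabs(ax[1]) + hs[2] * std::fabs(ax[2]);
      if (mn > rad || mx < -rad) return false;
    }
  // triangle plane
  double n[3];
  vcross(e[0], e[1], n);
  return planeBoxOverlap(n, v[0], hs);
}

// [[Rcpp::export]]
bool cpp_tribox_overlap(NumericMatrix tri, NumericVector bmin, NumericVector bmax) {
  double c[3], hs[3], t0[3], t1[3], t2[3];
  for (int q = 0; q < 3; q++) {
    c[q]  = 0.5 * (bmin[q] + bmax[q]);
    hs[q] = 0.5 * (bmax[q] - bmin[q]);
    t0[q] = tri(0, q); t1[q] = tri(1, q); t2[q] = tri(2, q);
  }
  return triBoxOverlap(c, hs, t0, t1, t2);
}

// ----------------------------------------------------------- surface voxelize
// [[Rcpp::export]]
LogicalVector cpp_surface_voxelize(NumericMatrix V, IntegerMatrix F,
                                   NumericVector origin, double h,
                                   IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  LogicalVector out(N, false);
  const int m = F.nrow();
  double t0[3], t1[3], t2[3], c[3];
  double hs[3] = { h / 2.0, h / 2.0, h / 2.0 };
  for (int f = 0; f < m; f++) {
    for (int q = 0; q < 3; q++) {
      t0[q] = V(F(f, 0) - 1, q);
      t1[q] = V(F(f, 1) - 1, q);
      t2[q] = V(F(f, 2) - 1, q);
    }
    int lo[3], hi[3];
    for (int q = 0; q < 3; q++) {
      double mn = std::min(t0[q], std::min(t1[q], t2[q]));
      double mx = std::max(t0[q], std::max(t1[q], t2[q]));
      lo[q] = (int)std::floor((mn - origin[q]) / h) - 1;
      hi[q] = (int)std::floor((mx - origin[q]) / h) + 1;
      int d = (q == 0) ? nx : (q == 1 ? ny : nz);
      if (lo[q] < 0) lo[q] = 0;
      if (hi[q] > d - 1) hi[q] = d - 1;
    }
    for (int z = lo[2]; z <= hi[2]; z++)
      for (int y = lo[1]; y <= hi[1]; y++)
        for (int x = lo[0]; x <= hi[0]; x++) {
          R_xlen_t idx = (R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
          if (out[idx]) continue;
          // box corners computed exactly as voxel_world_box() does, so the
          // result is bit-identical to the per-pair predicate at exact-touch
          // configurations
          int iv[3] = { x, y, z };
          for (int q = 0; q < 3; q++) {
            double bmin = origin[q] + iv[q] * h;
            double bmax = origin[q] + (iv[q] + 1) * h;
            c[q] = 0.5 * (bmin + bmax);
            hs[q] = 0.5 * (bmax - bmin);
          }
          if (triBoxOverlap(c, hs, t0, t1, t2)) out[idx] = true;
        }
  }
  return out;
}

// ------------------------------------------------------------ 2D flood fill
// Exterior = 4-connected flood from all border pixels through unset pixels.
// Output = input OR complement(exterior).
static void fill_slice(std::vector<char> &img, int nx, int ny) {
  std::vector<char> ext(img.size(), 0);
  std::vector<int> stack;
  stack.reserve(nx * ny / 4 + 8);
  auto push = [&](int x, int y) {
    int i = x + nx * y;
    if (!img[i] && !ext[i]) { ext[i] = 1; stack.push_back(i); }
  };
  for (int x = 0; x < nx; x++) { push(x, 0); push(x, ny - 1); }
  for (int y = 0; y < ny; y++) { push(0, y); push(nx - 1, y); }
  while (!stack.empty()) {
    int i = stack.back(); stack.pop_back();
    int x = i % nx, y = i / nx;
    if (x > 0)      push(x - 1, y);
    if (x < nx - 1) push(x + 1, y);
    if (y > 0)      push(x, y - 1);
    if (y < ny - 1) push(x, y + 1);
  }
  for (size_t i = 0; i < img.size(); i++)
    if (!ext[i]) img[i] = 1;
}

// [[Rcpp::export]]
LogicalMatrix cpp_flood_fill_slice(LogicalMatrix slice) {
  const int nx = slice.nrow(), ny = slice.ncol();
  std::vector<char> img((size_t)nx * ny);
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++)
      img[x + nx * y] = slice(x, y) ? 1 : 0;
  fill_slice(img, nx, ny);
  LogicalMatrix out(nx, ny);
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++)
      out(x, y) = img[x + nx * y] != 0;
  return out;
}

// Per-slice solid voxelization along one axis (0=x, 1=y, 2=z). Each slice is
// a pure function of its own pixels (parallelism contract).
// [[Rcpp::export]]
LogicalVector cpp_solid_axis(LogicalVector bits, IntegerVector dims, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out(bits.size());
  auto lin = [&](int x, int y, int z) -> R_xlen_t {
    return (R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
  };
  int n1, n2, ns;                 // in-slice dims and slice count
  if (axis == 0) { ns = nx; n1 = ny; n2 = nz; }
  else if (axis == 1) { ns = ny; n1 = nx; n2 = nz; }
  else { ns = nz; n1 = nx; n2 = ny; }
  std::vector<char> img((size_t)n1 * n2);
  for (int s = 0; s < ns; s++) {
    for (int b = 0; b < n2; b++)
      for (int a = 0; a < n1; a++) {
        R_xlen_t i = (axis == 0) ? lin(s, a, b) : (axis == 1) ? lin(a, s, b) : lin(a, b, s);
        img[a + (size_t)n1 * b] = bits[i] ? 1 : 0;
      }
    fill_slice(img, n1, n2);
    for (int b = 0; b < n2; b++)
      for (int a = 0; a < n1; a++) {
        R_xlen_t i = (axis == 0) ? lin(s, a, b) : (axis == 1) ? lin(a, s, b) : lin(a, b, s);
        out[i] = img[a + (size_t)n1 * b] != 0;
      }
  }
  return out;
}

// ---------------------------------------------------- marching tetrahedra MC
// Values sampled at voxel centres; cells between adjacent centres are split
// into 6 tetrahedra sharing the main diagonal, so shared cell faces receive
// the same diagonal from both sides and crossing vertices (cached per global
// sample-pair edge) are shared: the surface is closed on padded grids.
struct MTAcc {
  std::vector<double> vx;
  std::vector<int> tris;
  std::unordered_map<int64_t, int> edge_vertex;
};

static int mt_vertex(MTAcc &acc, int64_t ia, int64_t ib,
                     const double pa[3], const double pb[3],
                     double va, double vb, double iso) {
  if (ia > ib) { std::swap(ia, ib); const double *tp = pa; pa = pb; pb = tp; std::swap(va, vb); }
  int64_t key = ia * 0x100000000LL + ib;
  auto it = acc.edge_vertex.find(key);
  if (it != acc.edge_vertex.end()) return it->second;
  double t = (va == vb) ? 0.5 : (iso - va) / (vb - va);
  if (t < 0.0) t = 0.0; if (t > 1.0) t = 1.0;
  int id = (int)(acc.vx.size() / 3);
  for (int q = 0; q < 3; q++) acc.vx.push_back(pa[q] + t * (pb[q] - pa[q]));
  acc.edge_vertex[key] = id;
  return id;
}

static void mt_tri(MTAcc &acc, int a, int b, int c,
                   const double ref_in[3], const double ref_out[3]) {
  // orient so the normal points from the inside region towards the outside
  const double *p0 = &acc.vx[3 * (size_t)a], *p1 = &acc.vx[3 * (size_t)b],
               *p2 = &acc.vx[3 * (size_t)c];
  double e1[3], e2[3], n[3], d[3];
  for (int q = 0; q < 3; q++) { e1[q] = p1[q] - p0[q]; e2[q] = p2[q] - p0[q]; d[q] = ref_out[q] - ref_in[q]; }
  vcross(e1, e2, n);
  if (vdot(n, d) < 0.0) std::swap(b, c);
  acc.tris.push_back(a); acc.tris.push_back(b); acc.tris.push_back(c);
}

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector values, IntegerVector dims,
                       NumericVector origin, double h, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  static const int off[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  static const int tets[6][4] = {
    {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}};
  MTAcc acc;
  double P[8][3]; double v[8]; int64_t gid[8];
  for (int z = 0; z + 1 < nz; z++)
    for (int y = 0; y + 1 < ny; y++)
      for (int x = 0; x + 1 < nx; x++) {
        int nin = 0;
        for (int k = 0; k < 8; k++) {
          int cx = x + off[k][0], cy = y + off[k][1], cz = z + off[k][2];
          gid[k] = (int64_t)cx + (int64_t)nx * (cy + (int64_t)ny * cz);
          v[k] = values[(R_xlen_t)gid[k]];
          P[k][0] = origin[0] + (cx + 0.5) * h;
          P[k][1] = origin[1] + (cy + 0.5) * h;
          P[k][2] = origin[2] + (cz + 0.5) * h;
          if (v[k] > iso) nin++;
        }
        if (nin == 0 || nin == 8) continue;
        for (int tt = 0; tt < 6; tt++) {
          const int *T = tets[tt];
          int in[4], nin4 = 0, out[4], nout4 = 0;
          for (int k = 0; k < 4; k++) {
            if (v[T[k]] > iso) in[nin4++] = T[k]; else out[nout4++] = T[k];
          }
          if (nin4 == 0 || nin4 == 4) continue;
          if (nin4 == 1) {
            int A = in[0];
            int e0 = mt_vertex(acc, gid[A], gid[out[0]], P[A], P[out[0]], v[A], v[out[0]], iso);
            int e1 = mt_vertex(acc, gid[A], gid[out[1]], P[A], P[out[1]], v[A], v[out[1]], iso);
            int e2 = mt_vertex(acc, gid[A], gid[out[2]], P[A], P[out[2]], v[A], v[out[2]], iso);
            double co[3] = { (P[out[0]][0] + P[out[1]][0] + P[out[2]][0]) / 3.0,
                             (P[out[0]][1] + P[out[1]][1] + P[out[2]][1]) / 3.0,
                             (P[out[0]][2] + P[out[1]][2] + P[out[2]][2]) / 3.0 };
            mt_tri(acc, e0, e1, e2, P[A], co);
          } else if (nin4 == 3) {
            int D = out[0];
            int e0 = mt_vertex(acc, gid[D], gid[in[0]], P[D], P[in[0]], v[D], v[in[0]], iso);
            int e1 = mt_vertex(acc, gid[D], gid[in[1]], P[D], P[in[1]], v[D], v[in[1]], iso);
            int e2 = mt_vertex(acc, gid[D], gid[in[2]], P[D], P[in[2]], v[D], v[in[2]], iso);
            double ci[3] = { (P[in[0]][0] + P[in[1]][0] + P[in[2]][0]) / 3.0,
                             (P[in[0]][1] + P[in[1]][1] + P[in[2]][1]) / 3.0,
                             (P[in[0]][2] + P[in[1]][2] + P[in[2]][2]) / 3.0 };
            mt_tri(acc, e0, e1, e2, ci, P[D]);
          } else { // 2 in, 2 out -> quad eAC, eAD, eBD, eBC
            int A = in[0], B = in[1], C = out[0], D = out[1];
            int q0 = mt_vertex(acc, gid[A], gid[C], P[A], P[C], v[A], v[C], iso);
            int q1 = mt_vertex(acc, gid[A], gid[D], P[A], P[D], v[A], v[D], iso);
            int q2 = mt_vertex(acc, gid[B], gid[D], P[B], P[D], v[B], v[D], iso);
            int q3 = mt_vertex(acc, gid[B], gid[C], P[B], P[C], v[B], v[C], iso);
            double ci[3], co[3];
            for (int q = 0; q < 3; q++) {
              ci[q] = 0.5 * (P[A][q] + P[B][q]);
              co[q] = 0.5 * (P[C][q] + P[D][q]);
            }
            mt_tri(acc, q0, q1, q2, ci, co);
            mt_tri(acc, q0, q2, q3, ci, co);
          }
        }
      }
  int nv = (int)(acc.vx.size() / 3), nt = (int)(acc.tris.size() / 3);
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nt, 3);
  for (int i = 0; i < nv; i++)
    for (int q = 0; q < 3; q++) V(i, q) = acc.vx[3 * (size_t)i + q];
  for (int i = 0; i < nt; i++)
    for (int q = 0; q < 3; q++) F(i, q) = acc.tris[3 * (size_t)i + q] + 1;
  return List::create(_["vertices"] = V, _["triangles"] = F);
}

// ----------------------------------------------- dual contouring (DMC stand-in)
// One dual vertex per mixed cell (average of its cube-edge crossings); one
// quad per sign-change sample edge, split along its shorter diagonal.
// [[Rcpp::export]]
List cpp_dual_contour(NumericVector values, IntegerVector dims,
                      NumericVector origin, double h, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int cxn = nx - 1, cyn = ny - 1, czn = nz - 1;
  auto val = [&](int x, int y, int z) -> double {
    return values[(R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
  };
  auto cpos = [&](int x, int y, int z, double p[3]) {
    p[0] = origin[0] + (x + 0.5) * h;
    p[1] = origin[1] + (y + 0.5) * h;
    p[2] = origin[2] + (z + 0.5) * h;
  };
  static const int off[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  static const int cube_edges[12][2] = {
    {0,1},{1,2},{2,3},{3,0},{4,5},{5,6},{6,7},{7,4},{0,4},{1,5},{2,6},{3,7}};
  std::unordered_map<int64_t, int> cell_vertex;
  std::vector<double> vx;
  auto cell_id = [&](int cx, int cy, int cz) -> int64_t {
    return (int64_t)cx + (int64_t)cxn * (cy + (int64_t)cyn * cz);
  };
  auto dual_vertex = [&](int cx, int cy, int cz) -> int {
    int64_t id = cell_id(cx, cy, cz);
    auto it = cell_vertex.find(id);
    if (it != cell_vertex.end()) return it->second;
    double acc[3] = {0, 0, 0}; int nacc = 0;
    double p[8][3]; double v[8];
    for (int k = 0; k < 8; k++) {
      int x = cx + off[k][0], y = cy + off[k][1], z = cz + off[k][2];
      v[k] = val(x, y, z);
      cpos(x, y, z, p[k]);
    }
    for (int e = 0; e < 12; e++) {
      int a = cube_edges[e][0], b = cube_edges[e][1];
      bool ia = v[a] > iso, ib = v[b] > iso;
      if (ia == ib) continue;
      double t = (v[a] == v[b]) ? 0.5 : (iso - v[a]) / (v[b] - v[a]);
      for (int q = 0; q < 3; q++) acc[q] += p[a][q] + t * (p[b][q] - p[a][q]);
      nacc++;
    }
    int idx = (int)(vx.size() / 3);
    for (int q = 0; q < 3; q++) vx.push_back(acc[q] / std::max(1, nacc));
    cell_vertex[id] = idx;
    return idx;
  };
  std::vector<int> tris;
  int nquads = 0;
  // axis: 0=x,1=y,2=z; (a,b,c) right-handed
  static const int boff[4][2] = { {-1,-1}, {0,-1}, {0,0}, {-1,0} };
  for (int axis = 0; axis < 3; axis++) {
    int ea[3] = {0,0,0}; ea[axis] = 1;
    int bax = (axis + 1) % 3, cax = (axis + 2) % 3;
    for (int z = 0; z < nz; z++)
      for (int y = 0; y < ny; y++)
        for (int x = 0; x < nx; x++) {
          int s0[3] = {x, y, z};
          int s1[3] = {x + ea[0], y + ea[1], z + ea[2]};
          if (s1[0] >= nx || s1[1] >= ny || s1[2] >= nz) continue;
          double v0 = val(s0[0], s0[1], s0[2]), v1 = val(s1[0], s1[1], s1[2]);
          bool i0 = v0 > iso, i1 = v1 > iso;
          if (i0 == i1) continue;
          int q[4]; bool ok = true;
          for (int k = 0; k < 4; k++) {
            int cc[3] = { s0[0], s0[1], s0[2] };
            cc[bax] += boff[k][0];
            cc[cax] += boff[k][1];
            cc[axis] = s0[axis];
            if (cc[0] < 0 || cc[1] < 0 || cc[2] < 0 ||
                cc[0] >= cxn || cc[1] >= cyn || cc[2] >= czn) { ok = false; break; }
            q[k] = dual_vertex(cc[0], cc[1], cc[2]);
          }
          if (!ok) continue;           // shell touches grid boundary
          if (!i0) { std::swap(q[1], q[3]); } // inside at far end: flip winding
          nquads++;
          // split along shorter diagonal
          double d02 = 0, d13 = 0;
          for (int c = 0; c < 3; c++) {
            double a = vx[3 * (size_t)q[0] + c] - vx[3 * (size_t)q[2] + c];
            double b = vx[3 * (size_t)q[1] + c] - vx[3 * (size_t)q[3] + c];
            d02 += a * a; d13 += b * b;
          }
          if (d02 <= d13) {
            tris.push_back(q[0]); tris.push_back(q[1]); tris.push_back(q[2]);
            tris.push_back(q[0]); tris.push_back(q[2]); tris.push_back(q[3]);
          } else {
            tris.push_back(q[1]); tris.push_back(q[2]); tris.push_back(q[3]);
            tris.push_back(q[1]); tris.push_back(q[3]); tris.push_back(q[0]);
          }
        }
  }
  int nv = (int)(vx.size() / 3), nt = (int)(tris.size() / 3);
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nt, 3);
  for (int i = 0; i < nv; i++)
    for (int c = 0; c < 3; c++) V(i, c) = vx[3 * (size_t)i + c];
  for (int i = 0; i < nt; i++)
    for (int c = 0; c < 3; c++) F(i, c) = tris[3 * (size_t)i + c] + 1;
  return List::create(_["vertices"] = V, _["triangles"] = F,
                      _["n_quads"] = nquads);
}

// ------------------------------------------- triangle-triangle intersection
// Moller-style interval test; coplanar pairs fall back to a 2D overlap test.
static const double TT_EPS = 1e-9;

static bool edge_edge_2d(const double a0[2], const double a1[2],
                         const double b0[2], const double b1[2]) {
  double d1[2] = { a1[0] - a0[0], a1[1] - a0[1] };
  double d2[2] = { b1[0] - b0[0], b1[1] - b0[1] };
  double denom = d1[0] * d2[1] - d1[1] * d2[0];
  double dx = b0[0] - a0[0], dy = b0[1] - a0[1];
  if (std::fabs(denom) < 1e-14) return false;
  double t = (dx * d2[1] - dy * d2[0]) / denom;
  double s = (dx * d1[1] - dy * d1[0]) / denom;
  return t >= -TT_EPS && t <= 1 + TT_EPS && s >= -TT_EPS && s <= 1 + TT_EPS;
}
static bool point_in_tri_2d(const double p[2], const double a[2],
                            const double b[2], const double c[2]) {
  double d1 = (p[0]-b[0])*(a[1]-b[1]) - (a[0]-b[0])*(p[1]-b[1]);
  double d2 = (p[0]-c[0])*(b[1]-c[1]) - (b[0]-c[0])*(p[1]-c[1]);
  double d3 = (p[0]-a[0])*(c[1]-a[1]) - (c[0]-a[0])*(p[1]-a[1]);
  bool neg = (d1 < 0) || (d2 < 0) || (d3 < 0);
  bool pos = (d1 > 0) || (d2 > 0) || (d3 > 0);
  return !(neg && pos);
}
static bool coplanar_tri_tri(const double n[3],
                             const double u0[3], const double u1[3], const double u2[3],
                             const double w0[3], const double w1[3], const double w2[3]) {
  // project to the plane where n is largest
  int i0, i1;
  double a[3] = { std::fabs(n[0]), std::fabs(n[1]), std::fabs(n[2]) };
  if (a[0] > a[1] && a[0] > a[2]) { i0 = 1; i1 = 2; }
  else if (a[1] > a[2]) { i0 = 0; i1 = 2; }
  else { i0 = 0; i1 = 1; }
  double A[3][2] = { {u0[i0], u0[i1]}, {u1[i0], u1[i1]}, {u2[i0], u2[i1]} };
  double B[3][2] = { {w0[i0], w0[i1]}, {w1[i0], w1[i1]}, {w2[i0], w2[i1]} };
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++)
      if (edge_edge_2d(A[i], A[(i + 1) % 3], B[j], B[(j + 1) % 3])) return true;
  if (point_in_tri_2d(A[0], B[0], B[1], B[2])) return true;
  if (point_in_tri_2d(B[0], A[0], A[1], A[2])) return true;
  return false;
}

static bool tri_tri_intersect(const double v0[3], const double v1[3], const double v2[3],
                              const double u0[3], const double u1[3], const double u2[3]) {
  double e1[3], e2[3], n1[3], n2[3];
  vsub(v1, v0, e1); vsub(v2, v0, e2); vcross(e1, e2, n1);
  double d1 = -vdot(n1, v0);
  double du0 = vdot(n1, u0) + d1, du1 = vdot(n1, u1) + d1, du2 = vdot(n1, u2) + d1;
  double scale1 = std::sqrt(vdot(n1, n1));
  double eps1 = TT_EPS * std::max(1.0, scale1);
  if (std::fabs(du0) < eps1) du0 = 0;
  if (std::fabs(du1) < eps1) du1 = 0;
  if (std::fabs(du2) < eps1) du2 = 0;
  double du0du1 = du0 * du1, du0du2 = du0 * du2;
  if (du0du1 > 0 && du0du2 > 0) return false;

  vsub(u1, u0, e1); vsub(u2, u0, e2); vcross(e1, e2, n2);
  double d2 = -vdot(n2, u0);
  double dv0 = vdot(n2, v0) + d2, dv1 = vdot(n2, v1) + d2, dv2 = vdot(n2, v2) + d2;
  double scale2 = std::sqrt(vdot(n2, n2));
  double eps2 = TT_EPS * std::max(1.0, scale2);
  if (std::fabs(dv0) < eps2) dv0 = 0;
  if (std::fabs(dv1) < eps2) dv1 = 0;
  if (std::fabs(dv2) < eps2) dv2 = 0;
  double dv0dv1 = dv0 * dv1, dv0dv2 = dv0 * dv2;
  if (dv0dv1 > 0 && dv0dv2 > 0) return false;

  double D[3];
  vcross(n1, n2, D);
  double max = std::fabs(D[0]); int index = 0;
  double bb = std::fabs(D[1]), cc = std::fabs(D[2]);
  if (bb > max) { max = bb; index = 1; }
  if (cc > max) { max = cc; index = 2; }
  if (max < 1e-12 * std::max(1.0, scale1 * scale2)) {
    if (du0 == 0 && du1 == 0 && du2 == 0)
      return coplanar_tri_tri(n1, v0, v1, v2, u0, u1, u2);
    return false;
  }
  double vp0 = v0[index], vp1 = v1[index], vp2 = v2[index];
  double up0 = u0[index], up1 = u1[index], up2 = u2[index];

  auto intervals = [](double VV0, double VV1, double VV2,
                      double D0, double D1, double D2,
                      double D0D1, double D0D2,
                      double &isect0, double &isect1) -> bool {
    auto one = [&](double A, double B, double C, double X0, double X1) {
      double t1 = A + (B - A) * X0, t2 = A + (C - A) * X1;
      isect0 = std::min(t1, t2); isect1 = std::max(t1, t2);
    };
    if (D0D1 > 0) { one(VV2, VV0, VV1, D2 / (D2 - D0), D2 / (D2 - D1)); }
    else if (D0D2 > 0) { one(VV1, VV0, VV2, D1 / (D1 - D0), D1 / (D1 - D2)); }
    else if (D1 * D2 > 0 || D0 != 0) { one(VV0, VV1, VV2, D0 / (D0 - D1), D0 / (D0 - D2)); }
    else if (D1 != 0) { one(VV1, VV0, VV2, D1 / (D1 - D0), D1 / (D1 - D2)); }
    else if (D2 != 0) { one(VV2, VV0, VV1, D2 / (D2 - D0), D2 / (D2 - D1)); }
    else return false; // coplanar
    return true;
  };
  double is0[2], is1[2];
  if (!intervals(vp0, vp1, vp2, dv0, dv1, dv2, dv0dv1, dv0dv2, is0[0], is0[1]))
    return coplanar_tri_tri(n1, v0, v1, v2, u0, u1, u2);
  if (!intervals(up0, up1, up2, du0, du1, du2, du0du1, du0du2, is1[0], is1[1]))
    return coplanar_tri_tri(n1, v0, v1, v2, u0, u1, u2);
  return !(is0[1] < is1[0] || is1[1] < is0[0]);
}

// [[Rcpp::export]]
bool cpp_tri_tri(NumericMatrix A, NumericMatrix B) {
  double a0[3], a1[3], a2[3], b0[3], b1[3], b2[3];
  for (int q = 0; q < 3; q++) {
    a0[q] = A(0, q); a1[q] = A(1, q); a2[q] = A(2, q);
    b0[q] = B(0, q); b1[q] = B(1, q); b2[q] = B(2, q);
  }
  return tri_tri_intersect(a0, a1, a2, b0, b1, b2);
}

// Spatially hashed pair search; identical output to the all-pairs test.
// [[Rcpp::export]]
IntegerMatrix cpp_self_intersections(NumericMatrix V, IntegerMatrix F) {
  const int m = F.nrow();
  std::vector<double> bmin(3 * m), bmax(3 * m);
  double gmin[3] = { R_PosInf, R_PosInf, R_PosInf };
  double gmax[3] = { R_NegInf, R_NegInf, R_NegInf };
  double mean_ext = 0;
  for (int f = 0; f < m; f++) {
    for (int q = 0; q < 3; q++) {
      double a = V(F(f, 0) - 1, q), b = V(F(f, 1) - 1, q), c = V(F(f, 2) - 1, q);
      double mn = std::min(a, std::min(b, c)), mx = std::max(a, std::max(b, c));
      bmin[3 * f + q] = mn; bmax[3 * f + q] = mx;
      gmin[q] = std::min(gmin[q], mn); gmax[q] = std::max(gmax[q], mx);
      mean_ext += (mx - mn);
    }
  }
  mean_ext /= std::max(1, 3 * m);
  double cell = std::max(mean_ext * 2.0, 1e-9);
  for (int q = 0; q < 3; q++)
    cell = std::max(cell, (gmax[q] - gmin[q]) / 256.0);
  std::unordered_map<int64_t, std::vector<int>> bins;
  auto key3 = [&](int x, int y, int z) -> int64_t {
    return ((int64_t)x * 73856093LL) ^ ((int64_t)y * 19349663LL) ^ ((int64_t)z * 83492791LL);
  };
  for (int f = 0; f < m; f++) {
    int lo[3], hi[3];
    for (int q = 0; q < 3; q++) {
      lo[q] = (int)std::floor((bmin[3 * f + q] - gmin[q]) / cell);
      hi[q] = (int)std::floor((bmax[3 * f + q] - gmin[q]) / cell);
    }
    for (int z = lo[2]; z <= hi[2]; z++)
      for (int y = lo[1]; y <= hi[1]; y++)
        for (int x = lo[0]; x <= hi[0]; x++)
          bins[key3(x, y, z)].push_back(f);
  }
  std::unordered_set<int64_t> seen;
  std::vector<std::pair<int, int>> hits;
  double T1[3][3], T2[3][3];
  for (auto &kv : bins) {
    std::vector<int> &lst = kv.second;
    for (size_t i = 0; i < lst.size(); i++)
      for (size_t j = i + 1; j < lst.size(); j++) {
        int f1 = std::min(lst[i], lst[j]), f2 = std::max(lst[i], lst[j]);
        if (f1 == f2) continue;
        int64_t pk = (int64_t)f1 * m + f2;
        if (!seen.insert(pk).second) continue;
        // skip adjacent triangles (shared vertex index)
        bool adj = false;
        for (int a = 0; a < 3 && !adj; a++)
          for (int b = 0; b < 3; b++)
            if (F(f1, a) == F(f2, b)) { adj = true; break; }
        if (adj) continue;
        // AABB reject
        bool apart = false;
        for (int q = 0; q < 3; q++)
          if (bmin[3 * f1 + q] > bmax[3 * f2 + q] || bmin[3 * f2 + q] > bmax[3 * f1 + q]) { apart = true; break; }
        if (apart) continue;
        for (int k = 0; k < 3; k++)
          for (int q = 0; q < 3; q++) {
            T1[k][q] = V(F(f1, k) - 1, q);
            T2[k][q] = V(F(f2, k) - 1, q);
          }
        if (tri_tri_intersect(T1[0], T1[1], T1[2], T2[0], T2[1], T2[2]))
          hits.push_back(std::make_pair(f1 + 1, f2 + 1));
      }
  }
  std::sort(hits.begin(), hits.end());
  IntegerMatrix out((int)hits.size(), 2);
  for (size_t i = 0; i < hits.size(); i++) {
    out(i, 0) = hits[i].first; out(i, 1) = hits[i].second;
  }
  return out;
}

// ------------------------------------------------ point/mesh distance queries
static double closest_dist2_point_tri(const double p[3], const double a[3],
                                      const double b[3], const double c[3]) {
  // Ericson, Real-Time Collision Detection, closest point on triangle
  double ab[3], ac[3], ap[3];
  vsub(b, a, ab); vsub(c, a, ac); vsub(p, a, ap);
  double d1 = vdot(ab, ap), d2 = vdot(ac, ap);
  double q[3];
  if (d1 <= 0 && d2 <= 0) { q[0]=a[0];q[1]=a[1];q[2]=a[2]; }
  else {
    double bp[3]; vsub(p, b, bp);
    double d3 = vdot(ab, bp), d4 = vdot(ac, bp);
    if (d3 >= 0 && d4 <= d3) { q[0]=b[0];q[1]=b[1];q[2]=b[2]; }
    else {
      double vc = d1 * d4 - d3 * d2;
      if (vc <= 0 && d1 >= 0 && d3 <= 0) {
        double w = d1 / (d1 - d3);
        for (int k=0;k<3;k++) q[k] = a[k] + w * ab[k];
      } else {
        double cp[3]; vsub(p, c, cp);
        double d5 = vdot(ab, cp), d6 = vdot(ac, cp);
        if (d6 >= 0 && d5 <= d6) { q[0]=c[0];q[1]=c[1];q[2]=c[2]; }
        else {
          double vb = d5 * d2 - d1 * d6;
          if (vb <= 0 && d2 >= 0 && d6 <= 0) {
            double w = d2 / (d2 - d6);
            for (int k=0;k<3;k++) q[k] = a[k] + w * ac[k];
          } else {
            double va = d3 * d6 - d5 * d4;
            if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              for (int k=0;k<3;k++) q[k] = b[k] + w * (c[k] - b[k]);
            } else {
              double denom = 1.0 / (va + vb + vc);
              double v = vb * denom, w = vc * denom;
              for (int k=0;k<3;k++) q[k] = a[k] + ab[k] * v + ac[k] * w;
            }
          }
        }
      }
    }
  }
  double dx = p[0]-q[0], dy = p[1]-q[1], dz = p[2]-q[2];
  return dx*dx + dy*dy + dz*dz;
}

// [[Rcpp::export]]
NumericVector cpp_min_dist_to_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int np = P.nrow(), m = F.nrow();
  std::vector<double> tv(9 * (size_t)m);
  for (int f = 0; f < m; f++)
    for (int k = 0; k < 3; k++)
      for (int q = 0; q < 3; q++)
        tv[9 * (size_t)f + 3 * k + q] = V(F(f, k) - 1, q);
  NumericVector out(np);
  for (int i = 0; i < np; i++) {
    double p[3] = { P(i, 0), P(i, 1), P(i, 2) };
    double best = R_PosInf;
    for (int f = 0; f < m; f++) {
      const double *t = &tv[9 * (size_t)f];
      double d2 = closest_dist2_point_tri(p, t, t + 3, t + 6);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Ray-parity containment; fixed irrational direction to dodge edge hits.
// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int np = P.nrow(), m = F.nrow();
  double dir[3] = { 0.57073270, 0.67225377, 0.47189273 };
  std::vector<double> tv(9 * (size_t)m);
  for (int f = 0; f < m; f++)
    for (int k = 0; k < 3; k++)
      for (int q = 0; q < 3; q++)
        tv[9 * (size_t)f + 3 * k + q] = V(F(f, k) - 1, q);
  LogicalVector out(np);
  for (int i = 0; i < np; i++) {
    double o[3] = { P(i, 0), P(i, 1), P(i, 2) };
    int hits = 0;
    for (int f = 0; f < m; f++) {
      const double *a = &tv[9 * (size_t)f], *b = a + 3, *c = a + 6;
      double e1[3], e2[3], pv[3], tvv[3], qv[3];
      vsub(b, a, e1); vsub(c, a, e2);
      vcross(dir, e2, pv);
      double det = vdot(e1, pv);
      if (std::fabs(det) < 1e-14) continue;
      double inv = 1.0 / det;
      vsub(o, a, tvv);
      double u = vdot(tvv, pv) * inv;
      if (u < 0 || u > 1) continue;
      vcross(tvv, e1, qv);
      double v = vdot(dir, qv) * inv;
      if (v < 0 || u + v > 1) continue;
      double t = vdot(e2, qv) * inv;
      if (t > 1e-12) hits++;
    }
    out[i] = (hits % 2) == 1;
  }
  return out;
}

// --------------------------------------------------- solid sphere rasterizer
// Conservative: a voxel is set iff its box intersects any sphere.
// [[Rcpp::export]]
LogicalVector cpp_rasterize_spheres(NumericMatrix C, NumericVector r,
                                    NumericVector origin, double h,
                                    IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((R_xlen_t)nx * ny * nz, false);
  for (int s = 0; s < C.nrow(); s++) {
    double cx = C(s, 0), cy = C(s, 1), cz = C(s, 2), rr = r[s];
    int lo[3], hi[3];
    double cc[3] = { cx, cy, cz };
    for (int q = 0; q < 3; q++) {
      int d = (q == 0) ? nx : (q == 1 ? ny : nz);
      lo[q] = std::max(0, (int)std::floor((cc[q] - rr - origin[q]) / h) - 1);
      hi[q] = std::min(d - 1, (int)std::floor((cc[q] + rr - origin[q]) / h) + 1);
    }
    for (int z = lo[2]; z <= hi[2]; z++)
      for (int y = lo[1]; y <= hi[1]; y++)
        for (int x = lo[0]; x <= hi[0]; x++) {
          double bx0 = origin[0] + x * h, by0 = origin[1] + y * h, bz0 = origin[2] + z * h;
          double px = std::min(std::max(cx, bx0), bx0 + h);
          double py = std::min(std::max(cy, by0), by0 + h);
          double pz = std::min(std::max(cz, bz0), bz0 + h);
          double dx = px - cx, dy = py - cy, dz = pz - cz;
          if (dx*dx + dy*dy + dz*dz <= rr*rr)
            out[(R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = true;
        }
  }
  return out;
}
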