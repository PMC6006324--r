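#include <Rcpp.h>
#include <cmath>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Marching tetrahedra isosurface extraction on a 3D scalar grid.
// Each cube is split into 6 tetrahedra around the (0,0,0)-(1,1,1) diagonal;
// crossing vertices are shared via an edge hash.  Triangle winding is fixed
// afterwards against the field gradient so normals point towards decreasing
// field values (outside, for a mask-like field).
// ---------------------------------------------------------------------------

struct Key {
  uint64_t k;
  bool operator==(const Key& o) const { return k == o.k; }
};
struct KeyHash {
  size_t operator()(const Key& a) const { return std::hash<uint64_t>()(a.k); }
};

// [[Rcpp::export]]
List march_tets_cpp(NumericVector field, IntegerVector dim, double iso) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  auto node = [&](int i, int j, int k) -> uint64_t {
    return (uint64_t)i + (uint64_t)nx * ((uint64_t)j + (uint64_t)ny * (uint64_t)k);
  };
  auto fval = [&](uint64_t id) -> double { return field[(R_xlen_t)id]; };

  static const int tets[6][4] = {
    {0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
    {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}};
  static const int corner[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};

  std::unordered_map<Key, int, KeyHash> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;

  auto edge_point = [&](uint64_t a, uint64_t b, double fa, double fb,
                        int ai, int aj, int ak, int bi, int bj, int bk) -> int {
    uint64_t lo = a < b ? a : b, hi = a < b ? b : a;
    Key key{lo * 0x100000000ULL ^ hi};
    // combine properly: (lo << 32) | hi would overflow for big grids; use map on pair
    key.k = lo * 2654435761ULL + hi * 40503ULL + (lo ^ hi);
    // to avoid collisions entirely, use exact packing when possible
    if (lo < (1ULL << 32) && hi < (1ULL << 32)) key.k = (lo << 32) | hi;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = (iso - fa) / (fb - fa);
    if (!std::isfinite(t)) t = 0.5;
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    vx.push_back(ai + t * (bi - ai));
    vy.push_back(aj + t * (bj - aj));
    vz.push_back(ak + t * (bk - ak));
    int id = (int)vx.size() - 1;
    edge_vertex.emplace(key, id);
    return id;
  };

  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        uint64_t cid[8]; double cf[8]; int ci[8][3];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + corner[c][0], jj = j + corner[c][1], kk = k + corner[c][2];
          cid[c] = node(ii, jj, kk);
          cf[c] = fval(cid[c]);
          ci[c][0] = ii; ci[c][1] = jj; ci[c][2] = kk;
          if (cf[c] > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int v[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int inside[4], nin = 0;
          for (int c = 0; c < 4; ++c) inside[c] = cf[v[c]] > iso ? 1 : 0;
          for (int c = 0; c < 4; ++c) nin += inside[c];
          if (nin == 0 || nin == 4) continue;
          int in_idx[4], out_idx[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            if (inside[c]) in_idx[ni++] = v[c]; else out_idx[no++] = v[c];
          }
          auto ep = [&](int a, int b) {
            return edge_point(cid[a], cid[b], cf[a], cf[b],
                              ci[a][0], ci[a][1], ci[a][2],
                              ci[b][0], ci[b][1], ci[b][2]);
          };
          if (nin == 1) {
            int a = in_idx[0];
            int p0 = ep(a, out_idx[0]), p1 = ep(a, out_idx[1]), p2 = ep(a, out_idx[2]);
            tri.push_back(p0); tri.push_back(p1); tri.push_back(p2);
          } else if (nin == 3) {
            int a = out_idx[0];
            int p0 = ep(a, in_idx[0]), p1 = ep(a, in_idx[1]), p2 = ep(a, in_idx[2]);
            tri.push_back(p0); tri.push_back(p1); tri.push_back(p2);
          } else {  // 2 in, 2 out -> quad, split into two triangles
            int a = in_idx[0], b = in_idx[1], c = out_idx[0], d = out_idx[1];
            int pac = ep(a, c), pad = ep(a, d), pbc = ep(b, c), pbd = ep(b, d);
            tri.push_back(pac); tri.push_back(pad); tri.push_back(pbd);
            tri.push_back(pac); tri.push_back(pbd); tri.push_back(pbc);
          }
        }
      }
    }
  }

  const int nv = (int)vx.size();
  const int nt = (int)tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int a = 0; a < nv; ++a) { V(a,0) = vx[a]; V(a,1) = vy[a]; V(a,2) = vz[a]; }
  IntegerMatrix T(nt, 3);

  // orient each triangle so its normal points down the field gradient
  auto grad_at = [&](double x, double y, double z, double g[3]) {
    int i = (int)std::round(x), j = (int)std::round(y), kk2 = (int)std::round(z);
    if (i < 1) i = 1; if (i > nx - 2) i = nx - 2;
    if (j < 1) j = 1; if (j > ny - 2) j = ny - 2;
    if (kk2 < 1) kk2 = 1; if (kk2 > nz - 2) kk2 = nz - 2;
    g[0] = fval(node(i + 1, j, kk2)) - fval(node(i - 1, j, kk2));
    g[1] = fval(node(i, j + 1, kk2)) - fval(node(i, j - 1, kk2));
    g[2] = fval(node(i, j, kk2 + 1)) - fval(node(i, j, kk2 - 1));
  };
  for (int t = 0; t < nt; ++t) {
    int a = tri[3*t], b = tri[3*t+1], c = tri[3*t+2];
    double ux = vx[b]-vx[a], uy = vy[b]-vy[a], uz = vz[b]-vz[a];
    double wx2 = vx[c]-vx[a], wy2 = vy[c]-vy[a], wz2 = vz[c]-vz[a];
    double nxx = uy*wz2 - uz*wy2, nyy = uz*wx2 - ux*wz2, nzz = ux*wy2 - uy*wx2;
    double cxx = (vx[a]+vx[b]+vx[c])/3.0, cyy = (vy[a]+vy[b]+vy[c])/3.0,
           czz = (vz[a]+vz[b]+vz[c])/3.0;
    double g[3]; grad_at(cxx, cyy, czz, g);
    double d = nxx*g[0] + nyy*g[1] + nzz*g[2];
    if (d > 0) { int tmp = b; b = c; c = tmp; }  // normal must oppose gradient
    T(t,0) = a + 1; T(t,1) = b + 1; T(t,2) = c + 1;  // 1-based for R
  }
  return List::create(_["vertices"] = V, _["triangles"] = T);
}

// ---------------------------------------------------------------------------
// Brute-force nearest neighbour between point sets.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List nn_index_cpp(NumericMatrix query, NumericMatrix ref) {
  const int n = query.nrow(), m = ref.nrow();
  IntegerVector idx(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    double qx = query(i,0), qy = query(i,1), qz = query(i,2);
    double best = R_PosInf; int bj = 0;
    for (int j = 0; j < m; ++j) {
      double dx = ref(j,0)-qx, dy = ref(j,1)-qy, dz = ref(j,2)-qz;
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    idx[i] = bj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}

// ---------------------------------------------------------------------------
// Point-to-triangle-mesh distance (Ericson closest-point-on-triangle).
// ---------------------------------------------------------------------------
static double closest_point_tri(const double p[3], const double a[3],
                                const double b[3], const double c[3]) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i]=b[i]-a[i]; ac[i]=c[i]-a[i]; ap[i]=p[i]-a[i]; }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  auto dist2 = [&](double qx, double qy, double qz) {
    double dx=p[0]-qx, dy=p[1]-qy, dz=p[2]-qz; return dx*dx+dy*dy+dz*dz;
  };
  if (d1 <= 0 && d2 <= 0) return dist2(a[0],a[1],a[2]);
  double bp[3]; for (int i=0;i<3;++i) bp[i]=p[i]-b[i];
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) return dist2(b[0],b[1],b[2]);
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    return dist2(a[0]+v*ab[0], a[1]+v*ab[1], a[2]+v*ab[2]);
  }
  double cp[3]; for (int i=0;i<3;++i) cp[i]=p[i]-c[i];
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) return dist2(c[0],c[1],c[2]);
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    return dist2(a[0]+w*ac[0], a[1]+w*ac[1], a[2]+w*ac[2]);
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return dist2(b[0]+w*(c[0]-b[0]), b[1]+w*(c[1]-b[1]), b[2]+w*(c[2]-b[2]));
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return dist2(a[0]+ab[0]*v+ac[0]*w, a[1]+ab[1]*v+ac[1]*w, a[2]+ab[2]*v+ac[2]*w);
}

// [[Rcpp::export]]
NumericVector point_mesh_dist_cpp(NumericMatrix pts, NumericMatrix verts,
                                  IntegerMatrix tris) {
  const int n = pts.nrow(), nt = tris.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = {pts(i,0), pts(i,1), pts(i,2)};
    double best = R_PosInf;
    for (int t = 0; t < nt; ++t) {
      int a = tris(t,0)-1, b = tris(t,1)-1, c = tris(t,2)-1;
      double A[3] = {verts(a,0), verts(a,1), verts(a,2)};
      double B[3] = {verts(b,0), verts(b,1), verts(b,2)};
      double C[3] = {verts(c,0), verts(c,1), verts(c,2)};
      double d2 = closest_point_tri(p, A, B, C);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
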