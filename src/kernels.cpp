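// Geometry kernels: point-to-mesh closest point queries (used by ICP and
// footprint projection) and marching-tetrahedra polygonization of an
// implicit field (used by the synthetic femur generator).
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Closest point on triangle (a,b,c) to p.  Ericson-style Voronoi-region
// classification; exact up to floating point.
static inline void closest_pt_tri(const double *p, const double *a,
                                  const double *b, const double *c,
                                  double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }

  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }

  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v*ab[i];
    return;
  }

  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }

  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w*ac[i];
    return;
  }

  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w*(c[i] - b[i]);
    return;
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i]*v + ac[i]*w;
}

// For each query point, the nearest point on the triangle mesh (V, F).
// F is 1-based (R convention).  Brute force over triangles with a
// per-triangle bounding-sphere rejection test.
// [[Rcpp::export]]
List mesh_closest_points_cpp(NumericMatrix Q, NumericMatrix V, IntegerMatrix F) {
  const int nq = Q.nrow(), nf = F.nrow();
  NumericMatrix P(nq, 3);
  NumericVector D(nq);
  IntegerVector TI(nq);

  // precompute triangle vertices (contiguous) + bounding sphere
  std::vector<double> tv(9 * nf), cen(3 * nf), rad(nf);
  for (int t = 0; t < nf; ++t) {
    for (int k = 0; k < 3; ++k) {
      int vi = F(t, k) - 1;
      for (int i = 0; i < 3; ++i) tv[9*t + 3*k + i] = V(vi, i);
    }
    double r2 = 0.0;
    for (int i = 0; i < 3; ++i)
      cen[3*t + i] = (tv[9*t + i] + tv[9*t + 3 + i] + tv[9*t + 6 + i]) / 3.0;
    for (int k = 0; k < 3; ++k) {
      double s = 0.0;
      for (int i = 0; i < 3; ++i) {
        double d = tv[9*t + 3*k + i] - cen[3*t + i];
        s += d * d;
      }
      if (s > r2) r2 = s;
    }
    rad[t] = std::sqrt(r2);
  }

  int warm = -1; // warm start: consecutive queries are spatially coherent
  for (int q = 0; q < nq; ++q) {
    double p[3] = { Q(q,0), Q(q,1), Q(q,2) };
    double best = R_PosInf, bestpt[3] = {0,0,0};
    int bestt = -1;
    double bestd = R_PosInf; // sqrt(best)
    if (warm >= 0) {
      double out[3];
      closest_pt_tri(p, &tv[9*warm], &tv[9*warm + 3], &tv[9*warm + 6], out);
      double d2 = 0.0;
      for (int i = 0; i < 3; ++i) {
        double d = p[i] - out[i];
        d2 += d * d;
      }
      best = d2;
      bestd = std::sqrt(d2);
      bestt = warm;
      for (int i = 0; i < 3; ++i) bestpt[i] = out[i];
    }
    for (int t = 0; t < nf; ++t) {
      if (t == warm) continue;
      double dc = 0.0;
      for (int i = 0; i < 3; ++i) {
        double d = p[i] - cen[3*t + i];
        dc += d * d;
      }
      double lower = std::sqrt(dc) - rad[t];
      if (lower > bestd) continue;
      double out[3];
      closest_pt_tri(p, &tv[9*t], &tv[9*t + 3], &tv[9*t + 6], out);
      double d2 = 0.0;
      for (int i = 0; i < 3; ++i) {
        double d = p[i] - out[i];
        d2 += d * d;
      }
      if (d2 < best) {
        best = d2;
        bestd = std::sqrt(d2);
        bestt = t;
        for (int i = 0; i < 3; ++i) bestpt[i] = out[i];
      }
    }
    for (int i = 0; i < 3; ++i) P(q, i) = bestpt[i];
    D[q] = bestd;
    TI[q] = bestt + 1;
    warm = bestt;
  }
  return List::create(_["points"] = P, _["distance"] = D, _["triangle"] = TI);
}

// ---- marching tetrahedra -------------------------------------------------
// Cube corners numbered c = dx + 2*dy + 4*dz; the six tetrahedra share the
// main diagonal 0-7, which makes face diagonals agree between neighbouring
// cubes, so the extracted surface is watertight whenever the isosurface
// stays inside the grid.
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
  {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}
};

struct MTState {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
};

static inline int edge_vert(MTState &st, uint64_t gi, uint64_t gj,
                            double fi, double fj,
                            const double *pi_, const double *pj_) {
  if (gi > gj) { std::swap(gi, gj); std::swap(fi, fj);
                 const double *tmp = pi_; pi_ = pj_; pj_ = tmp; }
  uint64_t key = gi * 0x100000000ULL + gj;
  auto it = st.edge_vertex.find(key);
  if (it != st.edge_vertex.end()) return it->second;
  double t = fi / (fi - fj); // iso = 0
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  st.vx.push_back(pi_[0] + t * (pj_[0] - pi_[0]));
  st.vy.push_back(pi_[1] + t * (pj_[1] - pi_[1]));
  st.vz.push_back(pi_[2] + t * (pj_[2] - pi_[2]));
  int id = (int)st.vx.size(); // 1-based
  st.edge_vertex[key] = id;
  return id;
}

static inline void add_tri(MTState &st, int a, int b, int c,
                           const double *gdir) {
  // orient so the normal points along gdir (inside -> outside)
  double ax = st.vx[a-1], ay = st.vy[a-1], az = st.vz[a-1];
  double ux = st.vx[b-1]-ax, uy = st.vy[b-1]-ay, uz = st.vz[b-1]-az;
  double wx = st.vx[c-1]-ax, wy = st.vy[c-1]-ay, wz = st.vz[c-1]-az;
  double nx = uy*wz - uz*wy, ny = uz*wx - ux*wz, nz = ux*wy - uy*wx;
  if (nx*gdir[0] + ny*gdir[1] + nz*gdir[2] < 0.0) std::swap(b, c);
  st.f0.push_back(a); st.f1.push_back(b); st.f2.push_back(c);
}

// [[Rcpp::export]]
List marching_tetrahedra_cpp(NumericVector field, NumericVector xs,
                             NumericVector ys, NumericVector zs) {
  const int nx = xs.size(), ny = ys.size(), nz = zs.size();
  MTState st;
  const double *f = field.begin();
  auto gid = [&](int i, int j, int k) -> uint64_t {
    return (uint64_t)i + (uint64_t)nx * ((uint64_t)j + (uint64_t)ny * (uint64_t)k);
  };

  double cp[8][3]; // corner positions
  double cf[8];
  uint64_t cg[8];

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        for (int c = 0; c < 8; ++c) {
          int dx = c & 1, dy = (c >> 1) & 1, dz = (c >> 2) & 1;
          cg[c] = gid(i + dx, j + dy, k + dz);
          cf[c] = f[cg[c]];
          cp[c][0] = xs[i + dx]; cp[c][1] = ys[j + dy]; cp[c][2] = zs[k + dz];
        }
        // quick reject: all same sign
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) (cf[c] < 0.0 ? any_in : any_out) = true;
        if (!any_in || !any_out) continue;

        for (int t = 0; t < 6; ++t) {
          const int *T = TETS[t];
          int ins[4], nin = 0, outs[4], nout = 0;
          for (int c = 0; c < 4; ++c) {
            if (cf[T[c]] < 0.0) ins[nin++] = T[c]; else outs[nout++] = T[c];
          }
          if (nin == 0 || nin == 4) continue;
          // gradient proxy: inside centroid -> outside centroid
          double gdir[3] = {0, 0, 0};
          for (int c = 0; c < nout; ++c)
            for (int d = 0; d < 3; ++d) gdir[d] += cp[outs[c]][d] / nout;
          for (int c = 0; c < nin; ++c)
            for (int d = 0; d < 3; ++d) gdir[d] -= cp[ins[c]][d] / nin;

          if (nin == 1) {
            int a = edge_vert(st, cg[ins[0]], cg[outs[0]], cf[ins[0]], cf[outs[0]], cp[ins[0]], cp[outs[0]]);
            int b = edge_vert(st, cg[ins[0]], cg[outs[1]], cf[ins[0]], cf[outs[1]], cp[ins[0]], cp[outs[1]]);
            int c = edge_vert(st, cg[ins[0]], cg[outs[2]], cf[ins[0]], cf[outs[2]], cp[ins[0]], cp[outs[2]]);
            add_tri(st, a, b, c, gdir);
          } else if (nin == 3) {
            int a = edge_vert(st, cg[ins[0]], cg[outs[0]], cf[ins[0]], cf[outs[0]], cp[ins[0]], cp[outs[0]]);
            int b = edge_vert(st, cg[ins[1]], cg[outs[0]], cf[ins[1]], cf[outs[0]], cp[ins[1]], cp[outs[0]]);
            int c = edge_vert(st, cg[ins[2]], cg[outs[0]], cf[ins[2]], cf[outs[0]], cp[ins[2]], cp[outs[0]]);
            add_tri(st, a, b, c, gdir);
          } else { // 2-2: quad split into two triangles
            int a = edge_vert(st, cg[ins[0]], cg[outs[0]], cf[ins[0]], cf[outs[0]], cp[ins[0]], cp[outs[0]]);
            int b = edge_vert(st, cg[ins[0]], cg[outs[1]], cf[ins[0]], cf[outs[1]], cp[ins[0]], cp[outs[1]]);
            int c = edge_vert(st, cg[ins[1]], cg[outs[1]], cf[ins[1]], cf[outs[1]], cp[ins[1]], cp[outs[1]]);
            int d = edge_vert(st, cg[ins[1]], cg[outs[0]], cf[ins[1]], cf[outs[0]], cp[ins[1]], cp[outs[0]]);
            add_tri(st, a, b, c, gdir);
            add_tri(st, a, c, d, gdir);
          }
        }
      }

  int nv = (int)st.vx.size(), nf2 = (int)st.f0.size();
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = st.vx[v]; V(v, 1) = st.vy[v]; V(v, 2) = st.vz[v];
  }
  IntegerMatrix Fm(nf2, 3);
  for (int t = 0; t < nf2; ++t) {
    Fm(t, 0) = st.f0[t]; Fm(t, 1) = st.f1[t]; Fm(t, 2) = st.f2[t];
  }
  return List::create(_["vertices"] = V, _["faces"] = Fm);
}
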