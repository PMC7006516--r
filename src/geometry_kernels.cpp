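#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exhaustive nearest-neighbour search. Desk-scale clouds (10^2..10^4 points)
// make the O(N*M) scan faster in practice than tree construction, and the
// result is exact by construction.
// [[Rcpp::export(name = ".nn_search_cpp")]]
List nn_search_cpp(NumericMatrix src, NumericMatrix tgt) {
  const int n = src.nrow(), m = tgt.nrow();
  IntegerVector idx(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    const double sx = src(i, 0), sy = src(i, 1), sz = src(i, 2);
    double best = R_PosInf;
    int bj = 0;
    for (int j = 0; j < m; ++j) {
      const double dx = tgt(j, 0) - sx, dy = tgt(j, 1) - sy, dz = tgt(j, 2) - sz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    idx[i] = bj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// Closest point on a triangle to point p (Ericson, Real-Time Collision
// Detection, ch. 5).
static inline void closest_on_tri(const double* p, const double* a,
                                  const double* b, const double* c,
                                  double* out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i]; }
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
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
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
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// Closest point on a triangle mesh surface for each query point, with a
// vertex-NN prewarm to prune triangles by a distance bound.
// [[Rcpp::export(name = ".closest_on_mesh_cpp")]]
List closest_on_mesh_cpp(NumericMatrix query, NumericMatrix verts,
                         IntegerMatrix faces) {
  const int n = query.nrow(), nf = faces.nrow(), nv = verts.nrow();
  NumericMatrix out(n, 3);
  NumericVector dist(n);
  // triangle centroids and circumscribing radii for pruning
  std::vector<double> cx(nf), cy(nf), cz(nf), rad(nf);
  for (int f = 0; f < nf; ++f) {
    const int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
    cx[f] = (verts(a,0) + verts(b,0) + verts(c,0)) / 3.0;
    cy[f] = (verts(a,1) + verts(b,1) + verts(c,1)) / 3.0;
    cz[f] = (verts(a,2) + verts(b,2) + verts(c,2)) / 3.0;
    double r2 = 0.0;
    const int vid[3] = {a, b, c};
    for (int k = 0; k < 3; ++k) {
      double dx = verts(vid[k],0) - cx[f], dy = verts(vid[k],1) - cy[f],
             dz = verts(vid[k],2) - cz[f];
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 > r2) r2 = d2;
    }
    rad[f] = std::sqrt(r2);
  }
  for (int i = 0; i < n; ++i) {
    const double p[3] = {query(i,0), query(i,1), query(i,2)};
    // upper bound from nearest vertex
    double best = R_PosInf;
    for (int v = 0; v < nv; ++v) {
      double dx = verts(v,0) - p[0], dy = verts(v,1) - p[1], dz = verts(v,2) - p[2];
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) best = d2;
    }
    double bestd = std::sqrt(best);
    double bp[3] = {p[0], p[1], p[2]};
    for (int f = 0; f < nf; ++f) {
      double dx = cx[f] - p[0], dy = cy[f] - p[1], dz = cz[f] - p[2];
      double dc = std::sqrt(dx*dx + dy*dy + dz*dz) - rad[f];
      if (dc > bestd) continue;
      const int a = faces(f,0) - 1, b = faces(f,1) - 1, c = faces(f,2) - 1;
      const double A[3] = {verts(a,0), verts(a,1), verts(a,2)};
      const double B[3] = {verts(b,0), verts(b,1), verts(b,2)};
      const double C[3] = {verts(c,0), verts(c,1), verts(c,2)};
      double q[3];
      closest_on_tri(p, A, B, C, q);
      double d2 = (q[0]-p[0])*(q[0]-p[0]) + (q[1]-p[1])*(q[1]-p[1]) +
                  (q[2]-p[2])*(q[2]-p[2]);
      double d = std::sqrt(d2);
      if (d <= bestd) { bestd = d; bp[0] = q[0]; bp[1] = q[1]; bp[2] = q[2]; }
    }
    out(i,0) = bp[0]; out(i,1) = bp[1]; out(i,2) = bp[2];
    dist[i] = bestd;
  }
  return List::create(_["point"] = out, _["distance"] = dist);
}

// Solid voxelization of a closed, oriented triangle mesh by vertical
// (+z) ray parity per grid column. Voxel centre convention: a centre is
// occupied iff it lies strictly inside the surface; centres are offset by
// ~1e-6 voxel in x/y to break ties with mesh edges deterministically.
// [[Rcpp::export(name = ".voxelize_cpp")]]
LogicalVector voxelize_cpp(NumericMatrix verts, IntegerMatrix faces,
                           NumericVector origin, double vs,
                           int nx, int ny, int nz) {
  const int nf = faces.nrow();
  LogicalVector occ(static_cast<R_xlen_t>(nx) * ny * nz, false);
  // deterministic sub-voxel tie-break offsets (irrational fractions)
  const double ox = vs * 1e-6 * 0.7548776662, oy = vs * 1e-6 * 0.5698402910;

  // Bin triangles by x-column range to avoid an all-columns scan.
  std::vector< std::vector<int> > colfaces(static_cast<size_t>(nx));
  std::vector<double> x0(nf), x1(nf), y0(nf), y1(nf);
  for (int f = 0; f < nf; ++f) {
    const int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
    x0[f] = std::min(std::min(verts(a, 0), verts(b, 0)), verts(c, 0));
    x1[f] = std::max(std::max(verts(a, 0), verts(b, 0)), verts(c, 0));
    y0[f] = std::min(std::min(verts(a, 1), verts(b, 1)), verts(c, 1));
    y1[f] = std::max(std::max(verts(a, 1), verts(b, 1)), verts(c, 1));
    int i0 = std::max(0, (int)std::floor((x0[f] - origin[0]) / vs - 1.0));
    int i1 = std::min(nx - 1, (int)std::ceil((x1[f] - origin[0]) / vs));
    for (int i = i0; i <= i1; ++i) colfaces[(size_t)i].push_back(f);
  }

  std::vector<double> zs;
  for (int ix = 0; ix < nx; ++ix) {
    const double px = origin[0] + (ix + 0.5) * vs + ox;
    const std::vector<int>& cand = colfaces[(size_t)ix];
    for (int iy = 0; iy < ny; ++iy) {
      const double py = origin[1] + (iy + 0.5) * vs + oy;
      zs.clear();
      for (size_t k = 0; k < cand.size(); ++k) {
        const int f = cand[k];
        if (px < x0[f] || px > x1[f] || py < y0[f] || py > y1[f]) continue;
        const int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
        const double ax = verts(a, 0), ay = verts(a, 1), az = verts(a, 2);
        const double bx = verts(b, 0), by = verts(b, 1), bz = verts(b, 2);
        const double cx = verts(c, 0), cy = verts(c, 1), cz = verts(c, 2);
        const double d = (by - cy) * (ax - cx) + (cx - bx) * (ay - cy);
        if (std::fabs(d) < 1e-300) continue;  // projection degenerate: no z-parity contribution
        const double l1 = ((by - cy) * (px - cx) + (cx - bx) * (py - cy)) / d;
        const double l2 = ((cy - ay) * (px - cx) + (ax - cx) * (py - cy)) / d;
        const double l3 = 1.0 - l1 - l2;
        if (l1 < 0.0 || l2 < 0.0 || l3 < 0.0) continue;
        zs.push_back(l1 * az + l2 * bz + l3 * cz);
      }
      if (zs.empty()) continue;
      std::sort(zs.begin(), zs.end());
      // a centre is inside iff an odd number of crossings lies at or above
      // its z (half-open in z; closed surfaces have even total crossings)
      size_t p = 0;
      for (int iz = 0; iz < nz; ++iz) {
        const double pz = origin[2] + (iz + 0.5) * vs;
        while (p < zs.size() && zs[p] < pz) ++p;
        if ((zs.size() - p) % 2 == 1)
          occ[(R_xlen_t)iz * nx * ny + (R_xlen_t)iy * nx + ix] = true;
      }
    }
  }
  return occ;
}
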