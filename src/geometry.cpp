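#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Closest point on triangle (v0,v1,v2) to p, Eberly's region decomposition.
// Writes the closest point into out[3], returns squared distance.
static double closest_point_triangle(const double *p,
                                     const double *v0, const double *v1,
                                     const double *v2, double *out) {
  double e0[3], e1[3], d[3];
  for (int i = 0; i < 3; ++i) {
    e0[i] = v1[i] - v0[i];
    e1[i] = v2[i] - v0[i];
    d[i]  = v0[i] - p[i];
  }
  double a = e0[0]*e0[0] + e0[1]*e0[1] + e0[2]*e0[2];
  double b = e0[0]*e1[0] + e0[1]*e1[1] + e0[2]*e1[2];
  double c = e1[0]*e1[0] + e1[1]*e1[1] + e1[2]*e1[2];
  double dd = e0[0]*d[0] + e0[1]*d[1] + e0[2]*d[2];
  double e = e1[0]*d[0] + e1[1]*d[1] + e1[2]*d[2];
  double det = a*c - b*b;
  double s = b*e - c*dd;
  double t = b*dd - a*e;

  if (s + t <= det) {
    if (s < 0.0) {
      if (t < 0.0) { // region 4
        if (dd < 0.0) {
          t = 0.0;
          s = (-dd >= a) ? 1.0 : -dd / a;
        } else {
          s = 0.0;
          if (e >= 0.0) t = 0.0;
          else t = (-e >= c) ? 1.0 : -e / c;
        }
      } else { // region 3
        s = 0.0;
        if (e >= 0.0) t = 0.0;
        else t = (-e >= c) ? 1.0 : -e / c;
      }
    } else if (t < 0.0) { // region 5
      t = 0.0;
      if (dd >= 0.0) s = 0.0;
      else s = (-dd >= a) ? 1.0 : -dd / a;
    } else { // region 0
      double inv = (det > 0.0) ? 1.0 / det : 0.0;
      s *= inv;
      t *= inv;
      if (det <= 0.0) { s = 0.0; t = 0.0; } // degenerate triangle: fall to v0
    }
  } else {
    if (s < 0.0) { // region 2
      double tmp0 = b + dd, tmp1 = c + e;
      if (tmp1 > tmp0) {
        double numer = tmp1 - tmp0, denom = a - 2.0*b + c;
        s = (numer >= denom) ? 1.0 : numer / denom;
        t = 1.0 - s;
      } else {
        s = 0.0;
        if (tmp1 <= 0.0) t = 1.0;
        else t = (e >= 0.0) ? 0.0 : -e / c;
      }
    } else if (t < 0.0) { // region 6
      double tmp0 = b + e, tmp1 = a + dd;
      if (tmp1 > tmp0) {
        double numer = tmp1 - tmp0, denom = a - 2.0*b + c;
        t = (numer >= denom) ? 1.0 : numer / denom;
        s = 1.0 - t;
      } else {
        t = 0.0;
        if (tmp1 <= 0.0) s = 1.0;
        else s = (dd >= 0.0) ? 0.0 : -dd / a;
      }
    } else { // region 1
      double numer = (c + e) - (b + dd);
      if (numer <= 0.0) s = 0.0;
      else {
        double denom = a - 2.0*b + c;
        s = (numer >= denom) ? 1.0 : numer / denom;
      }
      t = 1.0 - s;
    }
  }

  double d2 = 0.0;
  for (int i = 0; i < 3; ++i) {
    out[i] = v0[i] + s*e0[i] + t*e1[i];
    double diff = out[i] - p[i];
    d2 += diff * diff;
  }
  return d2;
}

// For each query point: closest point on the mesh surface, squared distance
// and face index. k_candidates > 0 prunes via the k nearest face centroids
// (exact for smooth meshes when k covers the local neighbourhood);
// k_candidates <= 0 or >= n_faces tests every face.
// [[Rcpp::export]]
List cpp_closest_points(NumericMatrix pts, NumericMatrix verts,
                        IntegerMatrix faces, int k_candidates) {
  const int np = pts.nrow(), nf = faces.nrow();
  NumericMatrix closest(np, 3);
  NumericVector dist(np);
  IntegerVector face_id(np);

  // face vertex pointers flattened
  std::vector<double> tv(9 * (size_t)nf);
  std::vector<double> cen(3 * (size_t)nf);
  for (int f = 0; f < nf; ++f) {
    for (int j = 0; j < 3; ++j) {
      int vi = faces(f, j); // 0-based
      tv[9*(size_t)f + 3*j + 0] = verts(vi, 0);
      tv[9*(size_t)f + 3*j + 1] = verts(vi, 1);
      tv[9*(size_t)f + 3*j + 2] = verts(vi, 2);
    }
    for (int i = 0; i < 3; ++i)
      cen[3*(size_t)f + i] = (tv[9*(size_t)f + i] + tv[9*(size_t)f + 3 + i] +
                              tv[9*(size_t)f + 6 + i]) / 3.0;
  }

  bool exact = (k_candidates <= 0 || k_candidates >= nf);

  // uniform grid over face centroids for candidate pruning
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  int gd[3] = {1, 1, 1};
  double h = 1.0;
  std::vector< std::vector<int> > cells;
  if (!exact) {
    for (int f = 0; f < nf; ++f)
      for (int i = 0; i < 3; ++i) {
        double c = cen[3*(size_t)f + i];
        if (c < lo[i]) lo[i] = c;
        if (c > hi[i]) hi[i] = c;
      }
    double vol = 1.0;
    for (int i = 0; i < 3; ++i) vol *= std::max(hi[i] - lo[i], 1e-6);
    h = std::cbrt(vol * 4.0 / nf);  // ~4 centroids per cell
    if (!(h > 0)) h = 1.0;
    size_t ncell = 1;
    for (int i = 0; i < 3; ++i) {
      gd[i] = std::max(1, (int)std::floor((hi[i] - lo[i]) / h) + 1);
      if (gd[i] > 256) gd[i] = 256;
      ncell *= gd[i];
    }
    cells.resize(ncell);
    for (int f = 0; f < nf; ++f) {
      int cc[3];
      for (int i = 0; i < 3; ++i) {
        cc[i] = (int)((cen[3*(size_t)f + i] - lo[i]) / h);
        if (cc[i] < 0) cc[i] = 0;
        if (cc[i] >= gd[i]) cc[i] = gd[i] - 1;
      }
      cells[cc[0] + (size_t)gd[0] * (cc[1] + (size_t)gd[1] * cc[2])].push_back(f);
    }
  }

  std::vector<int> cand;
  cand.reserve(256);
  int max_ring = std::max(gd[0], std::max(gd[1], gd[2]));

  for (int q = 0; q < np; ++q) {
    double p[3] = { pts(q,0), pts(q,1), pts(q,2) };
    double best = R_PosInf, bp[3] = {0,0,0};
    int bf = -1;
    double tmp[3];
    if (exact) {
      for (int f = 0; f < nf; ++f) {
        double d2 = closest_point_triangle(p, &tv[9*(size_t)f],
                                           &tv[9*(size_t)f+3], &tv[9*(size_t)f+6], tmp);
        if (d2 < best) { best = d2; bp[0]=tmp[0]; bp[1]=tmp[1]; bp[2]=tmp[2]; bf=f; }
      }
    } else {
      int pc[3];
      for (int i = 0; i < 3; ++i) {
        pc[i] = (int)((p[i] - lo[i]) / h);
        if (pc[i] < 0) pc[i] = 0;
        if (pc[i] >= gd[i]) pc[i] = gd[i] - 1;
      }
      cand.clear();
      int found_ring = -1;
      for (int s = 0; s <= max_ring; ++s) {
        // cells at Chebyshev distance s from pc
        for (int dx = -s; dx <= s; ++dx) {
          int cx = pc[0] + dx;
          if (cx < 0 || cx >= gd[0]) continue;
          for (int dy = -s; dy <= s; ++dy) {
            int cy = pc[1] + dy;
            if (cy < 0 || cy >= gd[1]) continue;
            bool face_xy = (std::abs(dx) == s || std::abs(dy) == s);
            for (int dz = -s; dz <= s; ++dz) {
              if (!face_xy && std::abs(dz) != s) continue;
              int cz = pc[2] + dz;
              if (cz < 0 || cz >= gd[2]) continue;
              const std::vector<int> &cl =
                cells[cx + (size_t)gd[0] * (cy + (size_t)gd[1] * cz)];
              cand.insert(cand.end(), cl.begin(), cl.end());
            }
          }
        }
        if ((int)cand.size() >= k_candidates && found_ring < 0) found_ring = s;
        // two safety rings beyond the ring where enough candidates appeared
        if (found_ring >= 0 && s >= found_ring + 2) break;
      }
      for (size_t j = 0; j < cand.size(); ++j) {
        int f = cand[j];
        double d2 = closest_point_triangle(p, &tv[9*(size_t)f],
                                           &tv[9*(size_t)f+3], &tv[9*(size_t)f+6], tmp);
        if (d2 < best) { best = d2; bp[0]=tmp[0]; bp[1]=tmp[1]; bp[2]=tmp[2]; bf=f; }
      }
    }
    closest(q,0)=bp[0]; closest(q,1)=bp[1]; closest(q,2)=bp[2];
    dist[q] = std::sqrt(best);
    face_id[q] = bf + 1; // 1-based for R
  }
  return List::create(_["points"] = closest, _["distance"] = dist,
                      _["face"] = face_id);
}

// 6-connected flood fill over zero voxels starting from every zero voxel on
// the grid border; returns logical vector marking reached ("outside") voxels.
// occ: integer 0/1 occupancy in column-major order, dims = c(nx, ny, nz).
// [[Rcpp::export]]
LogicalVector cpp_flood_outside(IntegerVector occ, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::queue<size_t> qq;

  auto idx = [&](int x, int y, int z) -> size_t {
    return (size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z);
  };
  auto push = [&](int x, int y, int z) {
    size_t i = idx(x, y, z);
    if (!seen[i] && occ[i] == 0) { seen[i] = 1; qq.push(i); }
  };

  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x)
        if (x == 0 || y == 0 || z == 0 || x == nx-1 || y == ny-1 || z == nz-1)
          push(x, y, z);

  while (!qq.empty()) {
    size_t i = qq.front(); qq.pop();
    int z = (int)(i / ((size_t)nx * ny));
    size_t r = i % ((size_t)nx * ny);
    int y = (int)(r / nx), x = (int)(r % nx);
    if (x > 0)      push(x-1, y, z);
    if (x < nx-1)   push(x+1, y, z);
    if (y > 0)      push(x, y-1, z);
    if (y < ny-1)   push(x, y+1, z);
    if (z > 0)      push(x, y, z-1);
    if (z < nz-1)   push(x, y, z+1);
  }

  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = (seen[i] != 0);
  return out;
}
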