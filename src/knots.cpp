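#include "common.h"
using namespace Rcpp;

// Knot analysis of a closed polygon:
//  1. KMT-style reduction: a vertex is elided when the triangle spanned by it
//     and its two neighbours is pierced by no other segment of the chain, a
//     move that preserves the knot type.
//  2. A crossing diagram is read off a random planar projection (retried when
//     the projection is degenerate).
//  3. The knot determinant |Delta(-1)| is the absolute determinant of a minor
//     of the (Goeritz-equivalent) crossing matrix with +2 at the overpass arc
//     and -1 at the two underpass arcs of each crossing; it is 1 for the
//     unknot, 3 for the trefoil, 5 for the figure-eight knot.

namespace {

inline double d3(const double* a, const double* b) {
  return std::sqrt((a[0]-b[0])*(a[0]-b[0]) + (a[1]-b[1])*(a[1]-b[1]) +
                   (a[2]-b[2])*(a[2]-b[2]));
}

inline double cross2(double ax, double ay, double bx, double by) {
  return ax * by - ay * bx;
}

// 2D point-in-triangle (closed, with tolerance)
bool pt_in_tri2(double px, double py, const double t[3][2], double tol) {
  double s1 = cross2(t[1][0]-t[0][0], t[1][1]-t[0][1], px-t[0][0], py-t[0][1]);
  double s2 = cross2(t[2][0]-t[1][0], t[2][1]-t[1][1], px-t[1][0], py-t[1][1]);
  double s3 = cross2(t[0][0]-t[2][0], t[0][1]-t[2][1], px-t[2][0], py-t[2][1]);
  bool neg = (s1 < -tol) || (s2 < -tol) || (s3 < -tol);
  bool pos = (s1 > tol) || (s2 > tol) || (s3 > tol);
  return !(neg && pos);
}

bool seg_seg2(double ax, double ay, double bx, double by,
              double cx, double cy, double dx, double dy, double tol) {
  double r1 = cross2(bx-ax, by-ay, cx-ax, cy-ay);
  double r2 = cross2(bx-ax, by-ay, dx-ax, dy-ay);
  double r3 = cross2(dx-cx, dy-cy, ax-cx, ay-cy);
  double r4 = cross2(dx-cx, dy-cy, bx-cx, by-cy);
  if (((r1 > tol && r2 < -tol) || (r1 < -tol && r2 > tol)) &&
      ((r3 > tol && r4 < -tol) || (r3 < -tol && r4 > tol)))
    return true;
  return false;
}

// segment q1-q2 against closed triangle (t0, t1, t2); conservative
bool seg_tri_intersect(const double* q1, const double* q2,
                       const double* t0, const double* t1, const double* t2) {
  double e1[3] = {t1[0]-t0[0], t1[1]-t0[1], t1[2]-t0[2]};
  double e2[3] = {t2[0]-t0[0], t2[1]-t0[1], t2[2]-t0[2]};
  double d[3] = {q2[0]-q1[0], q2[1]-q1[1], q2[2]-q1[2]};
  double h[3] = {d[1]*e2[2]-d[2]*e2[1], d[2]*e2[0]-d[0]*e2[2], d[0]*e2[1]-d[1]*e2[0]};
  double det = e1[0]*h[0] + e1[1]*h[1] + e1[2]*h[2];
  double scale = std::max({std::fabs(e1[0])+std::fabs(e2[0])+std::fabs(d[0]),
                           std::fabs(e1[1])+std::fabs(e2[1])+std::fabs(d[1]),
                           std::fabs(e1[2])+std::fabs(e2[2])+std::fabs(d[2]), 1.0});
  double tol = 1e-10 * scale * scale * scale;
  if (std::fabs(det) > tol) {
    double s[3] = {q1[0]-t0[0], q1[1]-t0[1], q1[2]-t0[2]};
    double u = (s[0]*h[0] + s[1]*h[1] + s[2]*h[2]) / det;
    double q[3] = {s[1]*e1[2]-s[2]*e1[1], s[2]*e1[0]-s[0]*e1[2], s[0]*e1[1]-s[1]*e1[0]};
    double v = (d[0]*q[0] + d[1]*q[1] + d[2]*q[2]) / det;
    double t = (e2[0]*q[0] + e2[1]*q[1] + e2[2]*q[2]) / det;
    double e = 1e-9;
    return (u >= -e && v >= -e && u + v <= 1.0 + e && t >= -e && t <= 1.0 + e);
  }
  // segment parallel to the triangle plane
  double n[3] = {e1[1]*e2[2]-e1[2]*e2[1], e1[2]*e2[0]-e1[0]*e2[2], e1[0]*e2[1]-e1[1]*e2[0]};
  double nn = std::sqrt(n[0]*n[0] + n[1]*n[1] + n[2]*n[2]);
  if (nn < 1e-14) return true;  // degenerate triangle: be conservative
  for (int k = 0; k < 3; ++k) n[k] /= nn;
  double h1 = n[0]*(q1[0]-t0[0]) + n[1]*(q1[1]-t0[1]) + n[2]*(q1[2]-t0[2]);
  double h2 = n[0]*(q2[0]-t0[0]) + n[1]*(q2[1]-t0[1]) + n[2]*(q2[2]-t0[2]);
  if (std::min(std::fabs(h1), std::fabs(h2)) > 1e-9 * std::max(scale, 1.0))
    return false;  // off-plane and parallel
  // coplanar: 2D overlap test on the dominant plane of n
  int ax = 0;
  double an = std::fabs(n[0]);
  if (std::fabs(n[1]) > an) { ax = 1; an = std::fabs(n[1]); }
  if (std::fabs(n[2]) > an) ax = 2;
  int u0 = (ax + 1) % 3, u1 = (ax + 2) % 3;
  double T[3][2] = {{t0[u0], t0[u1]}, {t1[u0], t1[u1]}, {t2[u0], t2[u1]}};
  double tol2 = 1e-12 * scale * scale;
  if (pt_in_tri2(q1[u0], q1[u1], T, tol2) || pt_in_tri2(q2[u0], q2[u1], T, tol2))
    return true;
  for (int k = 0; k < 3; ++k) {
    int k2 = (k + 1) % 3;
    if (seg_seg2(q1[u0], q1[u1], q2[u0], q2[u1],
                 T[k][0], T[k][1], T[k2][0], T[k2][1], tol2))
      return true;
  }
  return false;
}

}  // namespace

// Reduce a closed polygon by triangle elision; returns the reduced polygon.
// [[Rcpp::export]]
NumericMatrix kmt_reduce_cpp(NumericMatrix P, int max_passes = 200) {
  int n = P.nrow();
  if (n < 3) stop("polygon needs at least 3 vertices");
  std::vector<std::array<double, 3>> pts(n);
  for (int i = 0; i < n; ++i) pts[i] = {P(i, 0), P(i, 1), P(i, 2)};
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  for (int pass = 0; pass < max_passes; ++pass) {
    bool changed = false;
    int k = 0;
    while ((int)idx.size() > 3 && k < (int)idx.size()) {
      int M = idx.size();
      int kp = (k - 1 + M) % M, kn = (k + 1) % M;
      const double* a = pts[idx[kp]].data();
      const double* b = pts[idx[k]].data();
      const double* c = pts[idx[kn]].data();
      bool blocked = false;
      for (int j = 0; j < M && !blocked; ++j) {
        if (j == k || j == kp) continue;  // the two chain edges of the triangle
        int j2 = (j + 1) % M;
        double q1[3] = {pts[idx[j]][0], pts[idx[j]][1], pts[idx[j]][2]};
        double q2[3] = {pts[idx[j2]][0], pts[idx[j2]][1], pts[idx[j2]][2]};
        // segments adjacent to the triangle share a corner vertex; shrink the
        // shared end slightly so corner contact alone does not block elision
        double sh = 1e-7;
        if (j2 == kp) {
          for (int w = 0; w < 3; ++w) q2[w] += sh * (q1[w] - q2[w]);
        }
        if (j == kn) {
          for (int w = 0; w < 3; ++w) q1[w] += sh * (q2[w] - q1[w]);
        }
        if (seg_tri_intersect(q1, q2, a, b, c)) blocked = true;
      }
      if (!blocked) {
        idx.erase(idx.begin() + k);
        changed = true;
      } else {
        ++k;
      }
    }
    if (!changed) break;
  }
  NumericMatrix out(idx.size(), 3);
  for (size_t i = 0; i < idx.size(); ++i) {
    out(i, 0) = pts[idx[i]][0];
    out(i, 1) = pts[idx[i]][1];
    out(i, 2) = pts[idx[i]][2];
  }
  return out;
}

// Crossing diagram + determinant from a random projection.
// [[Rcpp::export]]
List knot_determinant_cpp(NumericMatrix P, int seed, int max_tries = 25) {
  int n = P.nrow();
  if (n < 3) stop("polygon needs at least 3 vertices");
  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> g(0.0, 1.0);
  double scale = 0;
  for (int i = 0; i < n; ++i)
    scale = std::max({scale, std::fabs(P(i,0)), std::fabs(P(i,1)), std::fabs(P(i,2))});
  if (scale <= 0) scale = 1.0;

  for (int attempt = 0; attempt < max_tries; ++attempt) {
    // random rotation from a normalized quaternion
    double q0 = g(rng), q1 = g(rng), q2 = g(rng), q3 = g(rng);
    double qn = std::sqrt(q0*q0 + q1*q1 + q2*q2 + q3*q3);
    q0 /= qn; q1 /= qn; q2 /= qn; q3 /= qn;
    double R[3][3] = {
      {1 - 2*(q2*q2 + q3*q3), 2*(q1*q2 - q0*q3), 2*(q1*q3 + q0*q2)},
      {2*(q1*q2 + q0*q3), 1 - 2*(q1*q1 + q3*q3), 2*(q2*q3 - q0*q1)},
      {2*(q1*q3 - q0*q2), 2*(q2*q3 + q0*q1), 1 - 2*(q1*q1 + q2*q2)}};
    std::vector<double> X(n), Y(n), Z(n);
    for (int i = 0; i < n; ++i) {
      X[i] = R[0][0]*P(i,0) + R[0][1]*P(i,1) + R[0][2]*P(i,2);
      Y[i] = R[1][0]*P(i,0) + R[1][1]*P(i,1) + R[1][2]*P(i,2);
      Z[i] = R[2][0]*P(i,0) + R[2][1]*P(i,1) + R[2][2]*P(i,2);
    }
    struct Crossing { double over_pos, under_pos; int sign; };
    std::vector<Crossing> cr;
    bool degenerate = false;
    double tolp = 1e-9;
    for (int i = 0; i < n && !degenerate; ++i) {
      int i2 = (i + 1) % n;
      for (int j = i + 1; j < n && !degenerate; ++j) {
        int j2 = (j + 1) % n;
        if (j == i2 || j2 == i) continue;  // adjacent segments
        double rx = X[i2]-X[i], ry = Y[i2]-Y[i];
        double sx = X[j2]-X[j], sy = Y[j2]-Y[j];
        double den = cross2(rx, ry, sx, sy);
        double qpx = X[j]-X[i], qpy = Y[j]-Y[i];
        if (std::fabs(den) < 1e-12 * scale * scale) {
          // parallel in projection: degenerate only if also collinear & close
          if (std::fabs(cross2(rx, ry, qpx, qpy)) < 1e-9 * scale * scale)
            degenerate = true;
          continue;
        }
        double t = cross2(qpx, qpy, sx, sy) / den;
        double u = cross2(qpx, qpy, rx, ry) / den;
        bool t_border = (std::fabs(t) < tolp || std::fabs(t - 1.0) < tolp);
        bool u_border = (std::fabs(u) < tolp || std::fabs(u - 1.0) < tolp);
        bool t_in = (t > tolp && t < 1.0 - tolp);
        bool u_in = (u > tolp && u < 1.0 - tolp);
        if ((t_border && (u_in || u_border)) || (u_border && t_in)) {
          degenerate = true;
          continue;
        }
        if (!t_in || !u_in) continue;
        double z1 = Z[i] + t * (Z[i2] - Z[i]);
        double z2 = Z[j] + u * (Z[j2] - Z[j]);
        if (std::fabs(z1 - z2) < 1e-9 * std::max(scale, 1.0)) {
          degenerate = true;
          continue;
        }
        Crossing c;
        int sgn = den > 0 ? 1 : -1;
        if (z1 > z2) {
          c.over_pos = i + t; c.under_pos = j + u; c.sign = sgn;
        } else {
          c.over_pos = j + u; c.under_pos = i + t; c.sign = sgn;
        }
        cr.push_back(c);
      }
    }
    if (degenerate) continue;
    int m = cr.size();
    if (m <= 2) {
      // any diagram with <= 2 crossings of a single closed curve is an unknot
      return List::create(_["determinant"] = 1.0, _["crossings"] = m,
                          _["tries"] = attempt + 1, _["ok"] = true);
    }
    // arcs delimited by underpasses, ordered along the curve
    std::vector<int> ord(m);
    for (int i = 0; i < m; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return cr[a].under_pos < cr[b].under_pos;
    });
    std::vector<double> upos(m);
    for (int i = 0; i < m; ++i) upos[i] = cr[ord[i]].under_pos;
    std::vector<int> under_rank(m);
    for (int i = 0; i < m; ++i) under_rank[ord[i]] = i;
    auto arc_of = [&](double p) {
      // arc j runs from under event j to under event j+1 (cyclic)
      int lo = std::upper_bound(upos.begin(), upos.end(), p) - upos.begin();
      return (lo - 1 + m) % m;
    };
    std::vector<std::vector<double>> Mx(m, std::vector<double>(m, 0.0));
    for (int k = 0; k < m; ++k) {
      int over = arc_of(cr[k].over_pos);
      int in = (under_rank[k] - 1 + m) % m;
      int out = under_rank[k];
      Mx[k][over] += 2.0;
      Mx[k][in] -= 1.0;
      Mx[k][out] -= 1.0;
    }
    // |det| of the (m-1) minor by Gaussian elimination
    int d = m - 1;
    double det = 1.0;
    for (int col = 0; col < d; ++col) {
      int piv = col;
      for (int r = col + 1; r < d; ++r)
        if (std::fabs(Mx[r][col]) > std::fabs(Mx[piv][col])) piv = r;
      if (std::fabs(Mx[piv][col]) < 1e-12) { det = 0.0; break; }
      if (piv != col) { std::swap(Mx[piv], Mx[col]); det = -det; }
      det *= Mx[col][col];
      for (int r = col + 1; r < d; ++r) {
        double f = Mx[r][col] / Mx[col][col];
        for (int cc = col; cc < d; ++cc) Mx[r][cc] -= f * Mx[col][cc];
      }
    }
    return List::create(_["determinant"] = std::round(std::fabs(det)),
                        _["crossings"] = m, _["tries"] = attempt + 1,
                        _["ok"] = true);
  }
  return List::create(_["determinant"] = NA_REAL, _["crossings"] = NA_INTEGER,
                      _["tries"] = max_tries, _["ok"] = false);
}
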