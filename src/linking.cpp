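#include "common.h"
using namespace Rcpp;

// Gauss linking number of two closed polygons, summed segment pair by segment
// pair with the exact closed form: each pair of line segments contributes the
// signed solid angle of the tetrahedron spanned by their endpoints
// (Klenin & Langowski, Biopolymers 54:307, method 1a). Exact for polygons,
// so the result is an integer up to floating-point error for disjoint curves.

namespace {

inline void vsub(const double* a, const double* b, double* o) {
  o[0] = a[0] - b[0]; o[1] = a[1] - b[1]; o[2] = a[2] - b[2];
}
inline void vcross(const double* a, const double* b, double* o) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}
inline double vdot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
inline bool vnorm(double* a) {
  double n = std::sqrt(vdot(a, a));
  if (n < 1e-14) return false;
  a[0] /= n; a[1] /= n; a[2] /= n;
  return true;
}
inline double casin(double x) {
  if (x > 1.0) x = 1.0;
  if (x < -1.0) x = -1.0;
  return std::asin(x);
}

// contribution of segment (p1,p2) x (p3,p4)
double seg_pair(const double* p1, const double* p2,
                const double* p3, const double* p4) {
  double r13[3], r14[3], r23[3], r24[3], r12[3], r34[3];
  vsub(p3, p1, r13); vsub(p4, p1, r14);
  vsub(p3, p2, r23); vsub(p4, p2, r24);
  vsub(p2, p1, r12); vsub(p4, p3, r34);
  double n1[3], n2[3], n3[3], n4[3];
  vcross(r13, r14, n1);
  vcross(r14, r24, n2);
  vcross(r24, r23, n3);
  vcross(r23, r13, n4);
  if (!vnorm(n1) || !vnorm(n2) || !vnorm(n3) || !vnorm(n4)) return 0.0;
  double omega = casin(vdot(n1, n2)) + casin(vdot(n2, n3)) +
                 casin(vdot(n3, n4)) + casin(vdot(n4, n1));
  double cr[3];
  vcross(r34, r12, cr);
  double sgn = vdot(cr, r13);
  if (sgn > 0) return omega / (4.0 * M_PI);
  if (sgn < 0) return -omega / (4.0 * M_PI);
  return 0.0;
}

double lk_polygons(const NumericMatrix& A, const NumericMatrix& B) {
  int n = A.nrow(), m = B.nrow();
  if (n < 3 || m < 3) stop("closed polygons need at least 3 vertices");
  std::vector<double> a(3 * n), b(3 * m);
  for (int i = 0; i < n; ++i) {
    a[3*i] = A(i, 0); a[3*i+1] = A(i, 1); a[3*i+2] = A(i, 2);
  }
  for (int i = 0; i < m; ++i) {
    b[3*i] = B(i, 0); b[3*i+1] = B(i, 1); b[3*i+2] = B(i, 2);
  }
  // shared vertex makes the Gauss integral singular
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      double dx = a[3*i] - b[3*j], dy = a[3*i+1] - b[3*j+1], dz = a[3*i+2] - b[3*j+2];
      if (dx*dx + dy*dy + dz*dz < 1e-20)
        stop("curves share a vertex; linking number undefined");
    }
  double lk = 0;
  for (int i = 0; i < n; ++i) {
    const double* p1 = &a[3 * i];
    const double* p2 = &a[3 * ((i + 1) % n)];
    for (int j = 0; j < m; ++j) {
      const double* p3 = &b[3 * j];
      const double* p4 = &b[3 * ((j + 1) % m)];
      lk += seg_pair(p1, p2, p3, p4);
    }
  }
  return lk;
}

}  // namespace

// [[Rcpp::export]]
double linking_number_cpp(NumericMatrix a, NumericMatrix b) {
  return lk_polygons(a, b);
}

// Pairwise linking matrix for rings extracted from one configuration.
// Ring pairs whose bounding spheres do not intersect cannot be linked
// (each curve then lies outside a ball containing the other, so one curve is
// contractible in the complement of the other) and are assigned Lk = 0
// without integration.
// [[Rcpp::export]]
NumericMatrix linking_matrix_cpp(NumericMatrix pos, List rings) {
  int nr = rings.size();
  NumericMatrix lk(nr, nr);
  std::vector<NumericMatrix> curves(nr);
  std::vector<std::array<double, 4>> bnd(nr);  // cx, cy, cz, radius
  for (int r = 0; r < nr; ++r) {
    IntegerVector ids = rings[r];
    NumericMatrix c(ids.size(), 3);
    double cx = 0, cy = 0, cz = 0;
    for (int i = 0; i < ids.size(); ++i) {
      int b = ids[i] - 1;
      c(i, 0) = pos(b, 0); c(i, 1) = pos(b, 1); c(i, 2) = pos(b, 2);
      cx += c(i, 0); cy += c(i, 1); cz += c(i, 2);
    }
    cx /= ids.size(); cy /= ids.size(); cz /= ids.size();
    double rad = 0;
    for (int i = 0; i < ids.size(); ++i) {
      double d = std::sqrt((c(i,0)-cx)*(c(i,0)-cx) + (c(i,1)-cy)*(c(i,1)-cy) +
                           (c(i,2)-cz)*(c(i,2)-cz));
      if (d > rad) rad = d;
    }
    curves[r] = c;
    bnd[r] = {cx, cy, cz, rad};
  }
  for (int i = 0; i < nr; ++i)
    for (int j = i + 1; j < nr; ++j) {
      double dx = bnd[i][0] - bnd[j][0], dy = bnd[i][1] - bnd[j][1],
             dz = bnd[i][2] - bnd[j][2];
      double cd = std::sqrt(dx*dx + dy*dy + dz*dz);
      double v = 0;
      if (cd <= bnd[i][3] + bnd[j][3])
        v = lk_polygons(curves[i], curves[j]);
      lk(i, j) = v;
      lk(j, i) = v;
    }
  return lk;
}
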