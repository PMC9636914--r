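#include "common.h"
using namespace Rcpp;

// Box descriptor: type 0 = spherical wall (radius), 1 = periodic cube (length),
// optionally with fixed repulsive mesh sites (escape experiments).
struct BoxDesc {
  int type;
  double radius;
  double length;
  NumericMatrix mesh; // may be 0-row
  bool has_mesh;
};

static BoxDesc box_from_list(const List& box) {
  BoxDesc b;
  std::string t = as<std::string>(box["type"]);
  b.type = (t == "sphere") ? 0 : 1;
  b.radius = box.containsElementNamed("radius") && box["radius"] != R_NilValue
    ? as<double>(box["radius"]) : 0.0;
  b.length = box.containsElementNamed("length") && box["length"] != R_NilValue
    ? as<double>(box["length"]) : 0.0;
  b.has_mesh = false;
  if (box.containsElementNamed("mesh") && box["mesh"] != R_NilValue) {
    b.mesh = as<NumericMatrix>(box["mesh"]);
    b.has_mesh = b.mesh.nrow() > 0;
  }
  return b;
}

inline void min_image(double d[3], const BoxDesc& b) {
  if (b.type == 1 && b.length > 0) {
    for (int k = 0; k < 3; ++k) {
      d[k] -= b.length * std::round(d[k] / b.length);
    }
  }
}

static void build_adj(const IntegerMatrix& bonds, int N,
                      std::vector<std::array<int, 2>>& nb) {
  nb.assign(N, {-1, -1});
  for (int e = 0; e < bonds.nrow(); ++e) {
    int i = bonds(e, 0) - 1, j = bonds(e, 1) - 1;
    if (i < 0 || j < 0 || i >= N || j >= N || i == j)
      stop("invalid bond (%d, %d)", i + 1, j + 1);
    for (int w = 0; w < 2; ++w) {
      int a = w == 0 ? i : j, o = w == 0 ? j : i;
      if (nb[a][0] == -1) nb[a][0] = o;
      else if (nb[a][1] == -1) nb[a][1] = o;
      else stop("bead %d has more than two bonds", a + 1);
    }
  }
}

// Full energy breakdown. WCA acts between all bead pairs (including bonded
// ones, the Kremer-Grest convention); FENE carries only the attractive log.
// [[Rcpp::export]]
List energy_components_cpp(NumericMatrix pos, IntegerMatrix bonds, List ff, List box) {
  ForcePars p = ff_from_list(ff);
  BoxDesc b = box_from_list(box);
  int N = pos.nrow();
  double e_wca = 0, e_fene = 0, e_bend = 0, e_wall = 0;
  double wcut2 = std::pow(2.0, 1.0 / 3.0) * p.sig * p.sig;

  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double d[3] = {pos(i,0)-pos(j,0), pos(i,1)-pos(j,1), pos(i,2)-pos(j,2)};
      min_image(d, b);
      double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
      if (r2 < wcut2) e_wca += wca_energy(r2, p.eps, p.sig);
    }
  }
  for (int e = 0; e < bonds.nrow(); ++e) {
    int i = bonds(e, 0) - 1, j = bonds(e, 1) - 1;
    double d[3] = {pos(i,0)-pos(j,0), pos(i,1)-pos(j,1), pos(i,2)-pos(j,2)};
    min_image(d, b);
    double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
    double ef = fene_energy(r2, p.fene_k, p.fene_r0);
    if (!R_FINITE(ef))
      stop("FENE bond %d-%d extended beyond r0 (r = %.4f)", i + 1, j + 1, std::sqrt(r2));
    e_fene += ef;
  }
  std::vector<std::array<int, 2>> nb;
  build_adj(bonds, N, nb);
  for (int v = 0; v < N; ++v) {
    if (nb[v][0] < 0 || nb[v][1] < 0) continue;
    int pr = nb[v][0], nx = nb[v][1];
    double a[3] = {pos(v,0)-pos(pr,0), pos(v,1)-pos(pr,1), pos(v,2)-pos(pr,2)};
    double c[3] = {pos(nx,0)-pos(v,0), pos(nx,1)-pos(v,1), pos(nx,2)-pos(v,2)};
    min_image(a, b); min_image(c, b);
    e_bend += bend_energy(a, c, p.bend_k);
  }
  if (b.type == 0) {
    double wcutd = std::pow(2.0, 1.0 / 6.0) * p.sig;
    for (int i = 0; i < N; ++i) {
      double r = std::sqrt(pos(i,0)*pos(i,0) + pos(i,1)*pos(i,1) + pos(i,2)*pos(i,2));
      double d = b.radius - r;
      if (d <= 0)
        stop("bead %d lies outside the confining sphere", i + 1);
      if (d < wcutd) e_wall += wca_energy(d * d, p.wall_eps, p.sig);
    }
  } else if (b.has_mesh) {
    for (int i = 0; i < N; ++i) {
      for (int s = 0; s < b.mesh.nrow(); ++s) {
        double d[3] = {pos(i,0)-b.mesh(s,0), pos(i,1)-b.mesh(s,1), pos(i,2)-b.mesh(s,2)};
        min_image(d, b);
        double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
        if (r2 < wcut2) e_wall += wca_energy(r2, p.wall_eps, p.sig);
      }
    }
  }
  return List::create(_["wca"] = e_wca, _["fene"] = e_fene, _["bend"] = e_bend,
                      _["wall"] = e_wall,
                      _["total"] = e_wca + e_fene + e_bend + e_wall);
}

// Bond + bending terms touching a set of beads: FENE bonds with at least one
// endpoint in the set, bending angles centered at a bead in the set. This is
// the quantity a rewiring move changes (WCA and wall depend on positions only).
// [[Rcpp::export]]
double local_bond_bend_cpp(NumericMatrix pos, IntegerMatrix bonds,
                           IntegerVector beads, List ff, List box) {
  ForcePars p = ff_from_list(ff);
  BoxDesc b = box_from_list(box);
  int N = pos.nrow();
  std::vector<bool> in(N, false);
  for (int k = 0; k < beads.size(); ++k) {
    int i = beads[k] - 1;
    if (i < 0 || i >= N) stop("bead id out of range");
    in[i] = true;
  }
  double e = 0;
  for (int k = 0; k < bonds.nrow(); ++k) {
    int i = bonds(k, 0) - 1, j = bonds(k, 1) - 1;
    if (!in[i] && !in[j]) continue;
    double d[3] = {pos(i,0)-pos(j,0), pos(i,1)-pos(j,1), pos(i,2)-pos(j,2)};
    min_image(d, b);
    double ef = fene_energy(d[0]*d[0] + d[1]*d[1] + d[2]*d[2], p.fene_k, p.fene_r0);
    if (!R_FINITE(ef)) stop("FENE bond %d-%d extended beyond r0", i + 1, j + 1);
    e += ef;
  }
  std::vector<std::array<int, 2>> nb;
  build_adj(bonds, N, nb);
  for (int v = 0; v < N; ++v) {
    if (!in[v] || nb[v][0] < 0 || nb[v][1] < 0) continue;
    int pr = nb[v][0], nx = nb[v][1];
    double a[3] = {pos(v,0)-pos(pr,0), pos(v,1)-pos(pr,1), pos(v,2)-pos(pr,2)};
    double c[3] = {pos(nx,0)-pos(v,0), pos(nx,1)-pos(v,1), pos(nx,2)-pos(v,2)};
    min_image(a, b); min_image(c, b);
    e += bend_energy(a, c, p.bend_k);
  }
  return e;
}
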