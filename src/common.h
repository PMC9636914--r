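#ifndef RECONRINGS_COMMON_H
#define RECONRINGS_COMMON_H

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <random>
#include <algorithm>

// Reduced Lennard-Jones units throughout: sigma = epsilon = kBT = m = 1,
// friction gamma = 1 so the Brownian time tauB equals one reduced time unit.

struct ForcePars {
  double eps;      // WCA well depth
  double sig;      // bead diameter
  double fene_k;   // FENE spring constant
  double fene_r0;  // FENE maximum extension
  double bend_k;   // Kratky-Porod stiffness K
  double wall_eps; // wall WCA depth
};

inline ForcePars ff_from_list(const Rcpp::List& ff) {
  ForcePars p;
  p.eps = Rcpp::as<double>(ff["wca_epsilon"]);
  p.sig = Rcpp::as<double>(ff["wca_sigma"]);
  p.fene_k = Rcpp::as<double>(ff["fene_k"]);
  p.fene_r0 = Rcpp::as<double>(ff["fene_r0"]);
  p.bend_k = Rcpp::as<double>(ff["bending_k"]);
  p.wall_eps = Rcpp::as<double>(ff["wall_epsilon"]);
  return p;
}

// WCA energy at squared distance r2 (cutoff 2^(1/6) sigma, shifted to 0 there)
inline double wca_energy(double r2, double eps, double sig) {
  double rc2 = std::pow(2.0, 1.0 / 3.0) * sig * sig;
  if (r2 >= rc2) return 0.0;
  double sr2 = sig * sig / r2;
  double sr6 = sr2 * sr2 * sr2;
  return 4.0 * eps * (sr6 * sr6 - sr6) + eps;
}

// FENE attractive part: -k/2 r0^2 ln(1 - (r/r0)^2); diverges at r >= r0
inline double fene_energy(double r2, double k, double r0) {
  double x = r2 / (r0 * r0);
  if (x >= 1.0) return R_PosInf;
  return -0.5 * k * r0 * r0 * std::log(1.0 - x);
}

// Bending energy K (1 - cos theta) for tangent vectors a (prev->v) and b (v->next)
inline double bend_energy(const double a[3], const double b[3], double K) {
  double na = std::sqrt(a[0]*a[0] + a[1]*a[1] + a[2]*a[2]);
  double nb = std::sqrt(b[0]*b[0] + b[1]*b[1] + b[2]*b[2]);
  if (na <= 0.0 || nb <= 0.0) return 0.0;
  double c = (a[0]*b[0] + a[1]*b[1] + a[2]*b[2]) / (na * nb);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return K * (1.0 - c);
}

#endif
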