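#include "common.h"
using namespace Rcpp;

// Langevin dynamics engine with optional bond-swap reconnection.
//
// Integrator: Gronbech-Jensen/Farago discretization of the Langevin equation,
// which reduces to plain velocity Verlet at gamma = 0. Reduced units
// (sigma = eps = kBT = m = 1, gamma = 1 => tauB = 1 reduced time unit).
//
// Neighbor search: Verlet pair list (skin 0.3 sigma) on top of a cell grid,
// rebuilt when the maximum displacement since the last build exceeds half the
// skin. The same list serves the WCA force loop and, at a smaller cutoff rc,
// the reconnection candidate search.

namespace {

struct Sim {
  int N;                       // mobile beads
  int M;                       // fixed mesh sites (escape mode)
  std::vector<double> x, y, z, vx, vy, vz, fx, fy, fz;
  std::vector<double> sx, sy, sz;   // mesh site coordinates
  std::vector<std::array<int, 2>> nb;
  ForcePars ff;
  int boxtype;                 // 0 sphere, 1 periodic
  double wallR, boxL;
  // neighbor lists: force pairs (WCA cutoff + skin) and, separately,
  // reconnection candidate pairs (rc + skin)
  double rlist, skin, skin_recon, rforce2, rrecon2;
  bool want_recon;
  std::vector<int> pi, pj;     // force pairs (j may index mesh sites as N + s)
  std::vector<int> qi, qj;     // reconnection candidate pairs (beads only)
  std::vector<double> rfx, rfy, rfz;
  // FENE energy lookup over r^2 (exact near the divergence)
  std::vector<double> fene_tab;
  double fene_dx = 0, fene_xmax = 0;
  // ring bookkeeping
  std::vector<int> ringid, ringpos, rlen;  // per-bead: ring id, position, ring length
  int next_ring_id = 0, n_rings = 0;
  // reconnection
  double rc2;
  int min_ring;
  double attempts = 0, accepts = 0;
  double epot = 0;
  std::mt19937_64 rng;
  std::normal_distribution<double> gauss{0.0, 1.0};
  std::uniform_real_distribution<double> unif{0.0, 1.0};

  void minim(double d[3]) const {
    if (boxtype == 1) {
      for (int k = 0; k < 3; ++k) d[k] -= boxL * std::round(d[k] / boxL);
    }
  }
  double dist2(int i, int j) const {
    double d[3] = {x[i] - x[j], y[i] - y[j], z[i] - z[j]};
    minim(d);
    return d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
  }
  void init_fene_tab() {
    int n = 4096;
    double r02 = ff.fene_r0 * ff.fene_r0;
    fene_xmax = 0.98 * r02;
    fene_dx = fene_xmax / n;
    fene_tab.resize(n + 2);
    for (int i = 0; i <= n + 1; ++i)
      fene_tab[i] = -0.5 * ff.fene_k * r02 *
        std::log(1.0 - std::min(i * fene_dx, fene_xmax * (n + 1.0) / n) / r02);
  }
  // FENE energy from r^2; +Inf at/beyond the divergence
  double fene_fast(double r2) const {
    if (r2 < fene_xmax) {
      double u = r2 / fene_dx;
      int i = (int)u;
      double f = u - i;
      return fene_tab[i] * (1.0 - f) + fene_tab[i + 1] * f;
    }
    double r02 = ff.fene_r0 * ff.fene_r0;
    if (r2 >= r02) return R_PosInf;
    return -0.5 * ff.fene_k * r02 * std::log(1.0 - r2 / r02);
  }
};

int traverse_assign(Sim& s, int start, int id) {
  int cur = start, prev = -1, pos = 0;
  do {
    s.ringid[cur] = id;
    s.ringpos[cur] = pos++;
    int nxt = (s.nb[cur][0] == prev) ? s.nb[cur][1] : s.nb[cur][0];
    prev = cur;
    cur = nxt;
  } while (cur != start && pos <= s.N);
  // second pass: record the cycle length on every member bead
  int L = pos;
  cur = start; prev = -1; pos = 0;
  do {
    s.rlen[cur] = L;
    int nxt = (s.nb[cur][0] == prev) ? s.nb[cur][1] : s.nb[cur][0];
    prev = cur;
    cur = nxt;
    pos++;
  } while (cur != start && pos <= s.N);
  return L;
}

void rebuild_rings(Sim& s) {
  s.ringid.assign(s.N, -1);
  s.ringpos.assign(s.N, -1);
  s.rlen.assign(s.N, 0);
  s.n_rings = 0;
  for (int start = 0; start < s.N; ++start) {
    if (s.ringid[start] != -1 || s.nb[start][0] < 0) continue;
    int L = traverse_assign(s, start, s.next_ring_id++);
    if (s.ringid[start] == -1 || L > s.N)
      stop("bond graph is not a union of cycles");
    s.n_rings++;
  }
}

// ring lengths of the current configuration, one entry per ring
std::vector<int> ring_lengths_now(const Sim& s) {
  std::vector<int> out;
  std::vector<char> seen(s.N, 0);
  for (int start = 0; start < s.N; ++start) {
    if (seen[start] || s.nb[start][0] < 0) continue;
    int cur = start, prev = -1, pos = 0;
    do {
      seen[cur] = 1;
      int nxt = (s.nb[cur][0] == prev) ? s.nb[cur][1] : s.nb[cur][0];
      prev = cur;
      cur = nxt;
      pos++;
    } while (cur != start && pos <= s.N);
    out.push_back(pos);
  }
  return out;
}

// Cell-grid pair list build
void build_pairs(Sim& s) {
  double span, lo;
  if (s.boxtype == 0) {
    span = 2.0 * (s.wallR + 1.0);
    lo = -(s.wallR + 1.0);
  } else {
    span = s.boxL;
    lo = -0.5 * s.boxL;
  }
  int nc = std::max(1, (int)std::floor(span / s.rlist));
  if (nc > 200) nc = 200;
  double cw = span / nc;
  int ntot = s.N + s.M;
  std::vector<int> head(nc * nc * nc, -1), nxt(ntot, -1);
  auto cellof = [&](double px, double py, double pz) {
    int cx = (int)std::floor((px - lo) / cw);
    int cy = (int)std::floor((py - lo) / cw);
    int cz = (int)std::floor((pz - lo) / cw);
    if (s.boxtype == 1) {
      cx = ((cx % nc) + nc) % nc; cy = ((cy % nc) + nc) % nc; cz = ((cz % nc) + nc) % nc;
    } else {
      cx = std::min(std::max(cx, 0), nc - 1);
      cy = std::min(std::max(cy, 0), nc - 1);
      cz = std::min(std::max(cz, 0), nc - 1);
    }
    return (cx * nc + cy) * nc + cz;
  };
  for (int i = 0; i < ntot; ++i) {
    double px = i < s.N ? s.x[i] : s.sx[i - s.N];
    double py = i < s.N ? s.y[i] : s.sy[i - s.N];
    double pz = i < s.N ? s.z[i] : s.sz[i - s.N];
    int c = cellof(px, py, pz);
    nxt[i] = head[c];
    head[c] = i;
  }
  s.pi.clear();
  s.pj.clear();
  s.qi.clear();
  s.qj.clear();
  auto coord = [&](int i, double d[3]) {
    if (i < s.N) { d[0] = s.x[i]; d[1] = s.y[i]; d[2] = s.z[i]; }
    else { d[0] = s.sx[i - s.N]; d[1] = s.sy[i - s.N]; d[2] = s.sz[i - s.N]; }
  };
  for (int cx = 0; cx < nc; ++cx)
    for (int cy = 0; cy < nc; ++cy)
      for (int cz = 0; cz < nc; ++cz) {
        int c = (cx * nc + cy) * nc + cz;
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dz = -1; dz <= 1; ++dz) {
              int ex = cx + dx, ey = cy + dy, ez = cz + dz;
              if (s.boxtype == 1) {
                ex = ((ex % nc) + nc) % nc; ey = ((ey % nc) + nc) % nc; ez = ((ez % nc) + nc) % nc;
              } else if (ex < 0 || ey < 0 || ez < 0 || ex >= nc || ey >= nc || ez >= nc)
                continue;
              int c2 = (ex * nc + ey) * nc + ez;
              if (c2 < c) continue;
              for (int i = head[c]; i != -1; i = nxt[i]) {
                int jstart = (c2 == c) ? nxt[i] : head[c2];
                for (int j = jstart; j != -1; j = nxt[j]) {
                  if (i >= s.N && j >= s.N) continue;  // site-site
                  double a[3], b[3];
                  coord(i, a); coord(j, b);
                  double d[3] = {a[0] - b[0], a[1] - b[1], a[2] - b[2]};
                  s.minim(d);
                  double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
                  if (r2 <= s.rforce2) {
                    s.pi.push_back(std::min(i, j));
                    s.pj.push_back(std::max(i, j));
                  }
                  if (s.want_recon && r2 <= s.rrecon2 && i < s.N && j < s.N) {
                    s.qi.push_back(std::min(i, j));
                    s.qj.push_back(std::max(i, j));
                  }
                }
              }
            }
      }
  s.rfx = s.x; s.rfy = s.y; s.rfz = s.z;
}

void maybe_rebuild(Sim& s) {
  double half = 0.5 * (s.want_recon ? std::min(s.skin, s.skin_recon) : s.skin);
  double lim = half * half;
  for (int i = 0; i < s.N; ++i) {
    double d[3] = {s.x[i] - s.rfx[i], s.y[i] - s.rfy[i], s.z[i] - s.rfz[i]};
    // no min-image here: displacement accumulates in real space between builds
    if (d[0] * d[0] + d[1] * d[1] + d[2] * d[2] > lim) {
      build_pairs(s);
      return;
    }
  }
}

void compute_forces(Sim& s) {
  std::fill(s.fx.begin(), s.fx.end(), 0.0);
  std::fill(s.fy.begin(), s.fy.end(), 0.0);
  std::fill(s.fz.begin(), s.fz.end(), 0.0);
  s.epot = 0;
  double sig2 = s.ff.sig * s.ff.sig;
  double wcut2 = std::pow(2.0, 1.0 / 3.0) * sig2;
  size_t np = s.pi.size();
  for (size_t k = 0; k < np; ++k) {
    int i = s.pi[k], j = s.pj[k];
    double ax, ay, az, bx, by, bz;
    ax = s.x[i]; ay = s.y[i]; az = s.z[i];
    if (j < s.N) { bx = s.x[j]; by = s.y[j]; bz = s.z[j]; }
    else { bx = s.sx[j - s.N]; by = s.sy[j - s.N]; bz = s.sz[j - s.N]; }
    double d[3] = {ax - bx, ay - by, az - bz};
    s.minim(d);
    double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
    if (r2 >= wcut2) continue;
    double eps = (j < s.N) ? s.ff.eps : s.ff.wall_eps;
    if (r2 < 1e-12) stop("beads %d and %d overlap", i + 1, j + 1);
    double sr2 = sig2 / r2;
    double sr6 = sr2 * sr2 * sr2;
    double coef = 24.0 * eps * (2.0 * sr6 * sr6 - sr6) / r2;
    s.fx[i] += coef * d[0]; s.fy[i] += coef * d[1]; s.fz[i] += coef * d[2];
    if (j < s.N) {
      s.fx[j] -= coef * d[0]; s.fy[j] -= coef * d[1]; s.fz[j] -= coef * d[2];
    }
    s.epot += 4.0 * eps * (sr6 * sr6 - sr6) + eps;
  }
  // FENE bonds
  double r02 = s.ff.fene_r0 * s.ff.fene_r0;
  for (int i = 0; i < s.N; ++i) {
    for (int w = 0; w < 2; ++w) {
      int j = s.nb[i][w];
      if (j <= i) continue;
      double d[3] = {s.x[i] - s.x[j], s.y[i] - s.y[j], s.z[i] - s.z[j]};
      s.minim(d);
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      double xr = r2 / r02;
      if (xr >= 1.0)
        stop("FENE bond %d-%d overextended (r = %.4f >= r0)", i + 1, j + 1, std::sqrt(r2));
      double coef = -s.ff.fene_k / (1.0 - xr);
      s.fx[i] += coef * d[0]; s.fy[i] += coef * d[1]; s.fz[i] += coef * d[2];
      s.fx[j] -= coef * d[0]; s.fy[j] -= coef * d[1]; s.fz[j] -= coef * d[2];
      s.epot += -0.5 * s.ff.fene_k * r02 * std::log(1.0 - xr);
    }
  }
  // bending
  if (s.ff.bend_k != 0.0) {
    for (int v = 0; v < s.N; ++v) {
      int p = s.nb[v][0], n = s.nb[v][1];
      if (p < 0 || n < 0) continue;
      double a[3] = {s.x[v] - s.x[p], s.y[v] - s.y[p], s.z[v] - s.z[p]};
      double b[3] = {s.x[n] - s.x[v], s.y[n] - s.y[v], s.z[n] - s.z[v]};
      s.minim(a); s.minim(b);
      double na2 = a[0]*a[0] + a[1]*a[1] + a[2]*a[2];
      double nb2 = b[0]*b[0] + b[1]*b[1] + b[2]*b[2];
      double na = std::sqrt(na2), nbm = std::sqrt(nb2);
      if (na < 1e-12 || nbm < 1e-12) continue;
      double dot = a[0]*b[0] + a[1]*b[1] + a[2]*b[2];
      double c = dot / (na * nbm);
      double K = s.ff.bend_k;
      double dcda[3], dcdb[3];
      for (int k = 0; k < 3; ++k) {
        dcda[k] = b[k] / (na * nbm) - c * a[k] / na2;
        dcdb[k] = a[k] / (na * nbm) - c * b[k] / nb2;
      }
      // F_p = -K dc/da ; F_n = +K dc/db ; F_v balances
      for (int k = 0; k < 3; ++k) {
        double fp = -K * dcda[k];
        double fn = K * dcdb[k];
        double* F = (k == 0) ? s.fx.data() : (k == 1 ? s.fy.data() : s.fz.data());
        F[p] += fp;
        F[n] += fn;
        F[v] += -(fp + fn);
      }
      double cc = c > 1.0 ? 1.0 : (c < -1.0 ? -1.0 : c);
      s.epot += K * (1.0 - cc);
    }
  }
  // spherical wall
  if (s.boxtype == 0) {
    double wcutd = std::pow(2.0, 1.0 / 6.0) * s.ff.sig;
    for (int i = 0; i < s.N; ++i) {
      double r = std::sqrt(s.x[i]*s.x[i] + s.y[i]*s.y[i] + s.z[i]*s.z[i]);
      double dd = s.wallR - r;
      if (dd <= 1e-9)
        stop("bead %d escaped the confining sphere (r = %.3f, R = %.3f)", i + 1, r, s.wallR);
      if (dd >= wcutd) continue;
      double sr2 = sig2 / (dd * dd);
      double sr6 = sr2 * sr2 * sr2;
      double dudd = -24.0 * s.ff.wall_eps * (2.0 * sr6 * sr6 - sr6) / dd;
      // force on bead = +dU/dd * r_hat... dU/dd < 0, push inward along -r_hat
      double coef = dudd / std::max(r, 1e-12);
      s.fx[i] += coef * s.x[i]; s.fy[i] += coef * s.y[i]; s.fz[i] += coef * s.z[i];
      s.epot += 4.0 * s.ff.wall_eps * (sr6 * sr6 - sr6) + s.ff.wall_eps;
    }
  }
}

inline double ebond(const Sim& s, int i, int j) {
  double r2 = s.dist2(i, j);
  double r02 = s.ff.fene_r0 * s.ff.fene_r0;
  if (r2 >= r02) return R_PosInf;
  return -0.5 * s.ff.fene_k * r02 * std::log(1.0 - r2 / r02);
}

inline double eangle(const Sim& s, int v, int u, int w) {
  if (u < 0 || w < 0) return 0.0;
  double a[3] = {s.x[v] - s.x[u], s.y[v] - s.y[u], s.z[v] - s.z[u]};
  double b[3] = {s.x[w] - s.x[v], s.y[w] - s.y[v], s.z[w] - s.z[v]};
  const_cast<Sim&>(s).minim(a);
  const_cast<Sim&>(s).minim(b);
  return bend_energy(a, b, s.ff.bend_k);
}

struct Accepted { int a, b, c, d; };

// legality + Metropolis for one proposal; e_ac and e_old (= FENE(a,b) +
// FENE(c,d)) are hoisted by the caller. Returns true if accepted.
bool consider_proposal(Sim& s, int a, int c, int b, int d,
                       double e_ac, double e_old) {
  if (b == d || b == c || d == a) return false;
  // split legality
  if (s.ringid[a] == s.ringid[c]) {
    int L = s.rlen[a];
    int pa = s.ringpos[a], pb = s.ringpos[b];
    int pc = s.ringpos[c], pd = s.ringpos[d];
    int sa = (pb == pa + 1 || pa - pb == L - 1) ? 1 : 0;
    int sc = (pd == pc + 1 || pc - pd == L - 1) ? 1 : 0;
    if (sa != sc) {  // split into two cycles
      int len1 = (sa == 0) ? pc - pa : pa - pc;  // forward contour separation
      if (len1 < 0) len1 += L;
      len1 += 1;
      int len2 = L - len1;
      if (len1 < s.min_ring || len2 < s.min_ring) return false;
    }
  }
  s.attempts += 1;
  double r2bd = s.dist2(b, d);
  double r02 = s.ff.fene_r0 * s.ff.fene_r0;
  if (r2bd >= r02) return false;               // FENE divergence: dE = +Inf
  double de = e_ac + s.fene_fast(r2bd) - e_old;
  // rewiring can lower the bending energy by at most 4 angles x 2K each
  if (de > 45.0 + 8.0 * s.ff.bend_k) return false;
  if (s.ff.bend_k != 0.0) {
    de += eangle(s, a, (s.nb[a][0] == b ? s.nb[a][1] : s.nb[a][0]), c) - eangle(s, a, s.nb[a][0], s.nb[a][1]);
    de += eangle(s, b, (s.nb[b][0] == a ? s.nb[b][1] : s.nb[b][0]), d) - eangle(s, b, s.nb[b][0], s.nb[b][1]);
    de += eangle(s, c, (s.nb[c][0] == d ? s.nb[c][1] : s.nb[c][0]), a) - eangle(s, c, s.nb[c][0], s.nb[c][1]);
    de += eangle(s, d, (s.nb[d][0] == c ? s.nb[d][1] : s.nb[d][0]), b) - eangle(s, d, s.nb[d][0], s.nb[d][1]);
  }
  if (de <= 0.0) return true;
  if (de > 45.0) return false;  // exp(-45) ~ 3e-20: below any attainable draw
  return s.unif(s.rng) < std::exp(-de);
}

void replace_nb(Sim& s, int v, int oldn, int newn) {
  if (s.nb[v][0] == oldn) s.nb[v][0] = newn;
  else if (s.nb[v][1] == oldn) s.nb[v][1] = newn;
  else stop("internal error: stale swap");
}

void apply_swap_internal(Sim& s, int a, int b, int c, int d) {
  replace_nb(s, a, b, c);
  replace_nb(s, c, d, a);
  replace_nb(s, b, a, d);
  replace_nb(s, d, c, b);
  int r1 = s.ringid[a], r2 = s.ringid[c];
  int old_count = (r1 == r2) ? 1 : 2;
  int id1 = s.next_ring_id++;
  traverse_assign(s, a, id1);
  int new_count = 1;
  if (s.ringid[b] != id1) {
    traverse_assign(s, b, s.next_ring_id++);
    new_count = 2;
  }
  s.n_rings += new_count - old_count;
}

void reconnection_sweep(Sim& s) {
  static std::vector<Accepted> acc;
  acc.clear();
  size_t np = s.qi.size();
  for (size_t k = 0; k < np; ++k) {
    int i = s.qi[k], j = s.qj[k];
    if (s.nb[i][0] == j || s.nb[i][1] == j) continue;  // already bonded
    if (s.nb[i][0] < 0 || s.nb[i][1] < 0 || s.nb[j][0] < 0 || s.nb[j][1] < 0) continue;
    double r2ij = s.dist2(i, j);
    if (r2ij > s.rc2) continue;
    double e_ac = s.fene_fast(r2ij);
    double e_i[2] = {s.fene_fast(s.dist2(i, s.nb[i][0])),
                     s.fene_fast(s.dist2(i, s.nb[i][1]))};
    double e_j[2] = {s.fene_fast(s.dist2(j, s.nb[j][0])),
                     s.fene_fast(s.dist2(j, s.nb[j][1]))};
    for (int wb = 0; wb < 2; ++wb)
      for (int wd = 0; wd < 2; ++wd) {
        int b = s.nb[i][wb], d = s.nb[j][wd];
        if (consider_proposal(s, i, j, b, d, e_ac, e_i[wb] + e_j[wd]))
          acc.push_back({i, b, j, d});
      }
  }
  if (acc.empty()) return;
  if (acc.size() > 1)
    std::shuffle(acc.begin(), acc.end(), s.rng);
  static std::vector<int> touched;
  touched.clear();
  for (const Accepted& p : acc) {
    bool clash = false;
    for (int t : touched)
      if (t == p.a || t == p.b || t == p.c || t == p.d) { clash = true; break; }
    if (clash) continue;
    // bonds must still be present (they are, unless a conflicting swap ran)
    apply_swap_internal(s, p.a, p.b, p.c, p.d);
    touched.push_back(p.a); touched.push_back(p.b);
    touched.push_back(p.c); touched.push_back(p.d);
    s.accepts += 1;
  }
}

}  // namespace

// [[Rcpp::export]]
List md_run_cpp(NumericMatrix pos, NumericMatrix vel, IntegerMatrix bonds,
                List ff, List box, double dt, double gamma, double temp,
                int n_steps, int sample_every,
                double wall_r_start, double wall_r_end, int ramp_steps,
                bool reconnect, double rc, int min_ring_length,
                int seed, bool store_frames, double count_radius) {
  Sim s;
  s.N = pos.nrow();
  s.ff = ff_from_list(ff);
  std::string btype = as<std::string>(box["type"]);
  s.boxtype = (btype == "sphere") ? 0 : 1;
  s.boxL = (s.boxtype == 1) ? as<double>(box["length"]) : 0.0;
  s.wallR = wall_r_start;
  s.M = 0;
  if (s.boxtype == 1 && box.containsElementNamed("mesh") && box["mesh"] != R_NilValue) {
    NumericMatrix mesh = as<NumericMatrix>(box["mesh"]);
    s.M = mesh.nrow();
    s.sx.resize(s.M); s.sy.resize(s.M); s.sz.resize(s.M);
    for (int i = 0; i < s.M; ++i) {
      s.sx[i] = mesh(i, 0); s.sy[i] = mesh(i, 1); s.sz[i] = mesh(i, 2);
    }
  }
  s.x.resize(s.N); s.y.resize(s.N); s.z.resize(s.N);
  s.vx.resize(s.N); s.vy.resize(s.N); s.vz.resize(s.N);
  s.fx.resize(s.N); s.fy.resize(s.N); s.fz.resize(s.N);
  for (int i = 0; i < s.N; ++i) {
    s.x[i] = pos(i, 0); s.y[i] = pos(i, 1); s.z[i] = pos(i, 2);
    s.vx[i] = vel(i, 0); s.vy[i] = vel(i, 1); s.vz[i] = vel(i, 2);
  }
  s.nb.assign(s.N, {-1, -1});
  for (int e = 0; e < bonds.nrow(); ++e) {
    int i = bonds(e, 0) - 1, j = bonds(e, 1) - 1;
    for (int w = 0; w < 2; ++w) {
      int a = w == 0 ? i : j, o = w == 0 ? j : i;
      if (s.nb[a][0] == -1) s.nb[a][0] = o;
      else if (s.nb[a][1] == -1) s.nb[a][1] = o;
      else stop("bead %d has more than two bonds", a + 1);
    }
  }
  s.rc2 = rc * rc;
  s.min_ring = min_ring_length;
  s.skin = 0.3;
  s.skin_recon = 0.15;
  s.want_recon = reconnect;
  double wcut = std::pow(2.0, 1.0 / 6.0) * s.ff.sig;
  s.rforce2 = (wcut + s.skin) * (wcut + s.skin);
  s.rrecon2 = (rc + s.skin_recon) * (rc + s.skin_recon);
  s.rlist = std::max(wcut + s.skin, reconnect ? rc + s.skin_recon : 0.0);
  s.init_fene_tab();
  s.rng.seed((uint64_t)seed);
  rebuild_rings(s);
  build_pairs(s);
  compute_forces(s);

  double b_gjf = 1.0 / (1.0 + gamma * dt / 2.0);
  double a_gjf = (1.0 - gamma * dt / 2.0) / (1.0 + gamma * dt / 2.0);
  double noise_sd = std::sqrt(2.0 * gamma * temp * dt);

  int nsamp = (sample_every > 0) ? n_steps / sample_every : 0;
  std::vector<double> smp_step, smp_nr, smp_att, smp_acc, smp_kin, smp_pot, smp_nin;
  List ring_lengths(nsamp);
  List frames(store_frames ? nsamp : 0);
  int isamp = 0;

  std::vector<double> bx(s.N), by(s.N), bz(s.N);
  for (int step = 1; step <= n_steps; ++step) {
    if (ramp_steps > 0 && s.boxtype == 0) {
      double frac = std::min(1.0, (double)step / ramp_steps);
      s.wallR = wall_r_start + frac * (wall_r_end - wall_r_start);
    } else {
      s.wallR = wall_r_end;
    }
    // GJF position update
    for (int i = 0; i < s.N; ++i) {
      double n1 = gamma > 0 ? s.gauss(s.rng) * noise_sd : 0.0;
      double n2 = gamma > 0 ? s.gauss(s.rng) * noise_sd : 0.0;
      double n3 = gamma > 0 ? s.gauss(s.rng) * noise_sd : 0.0;
      bx[i] = n1; by[i] = n2; bz[i] = n3;
      s.x[i] += b_gjf * dt * s.vx[i] + 0.5 * b_gjf * dt * dt * s.fx[i] + 0.5 * b_gjf * dt * n1;
      s.y[i] += b_gjf * dt * s.vy[i] + 0.5 * b_gjf * dt * dt * s.fy[i] + 0.5 * b_gjf * dt * n2;
      s.z[i] += b_gjf * dt * s.vz[i] + 0.5 * b_gjf * dt * dt * s.fz[i] + 0.5 * b_gjf * dt * n3;
    }
    std::vector<double> fox = s.fx, foy = s.fy, foz = s.fz;
    maybe_rebuild(s);
    compute_forces(s);
    for (int i = 0; i < s.N; ++i) {
      s.vx[i] = a_gjf * s.vx[i] + 0.5 * dt * (a_gjf * fox[i] + s.fx[i]) + b_gjf * bx[i];
      s.vy[i] = a_gjf * s.vy[i] + 0.5 * dt * (a_gjf * foy[i] + s.fy[i]) + b_gjf * by[i];
      s.vz[i] = a_gjf * s.vz[i] + 0.5 * dt * (a_gjf * foz[i] + s.fz[i]) + b_gjf * bz[i];
    }
    if (reconnect) reconnection_sweep(s);
    if (step % 1000 == 0) {
      for (int i = 0; i < s.N; ++i)
        if (!std::isfinite(s.x[i]) || !std::isfinite(s.vx[i]))
          stop("non-finite coordinate for bead %d at step %d", i + 1, step);
      checkUserInterrupt();
    }
    if (sample_every > 0 && step % sample_every == 0) {
      double kin = 0;
      for (int i = 0; i < s.N; ++i)
        kin += 0.5 * (s.vx[i]*s.vx[i] + s.vy[i]*s.vy[i] + s.vz[i]*s.vz[i]);
      smp_step.push_back(step);
      smp_nr.push_back(s.n_rings);
      smp_att.push_back(s.attempts);
      smp_acc.push_back(s.accepts);
      smp_kin.push_back(kin);
      smp_pot.push_back(s.epot);
      std::vector<int> lens = ring_lengths_now(s);
      std::sort(lens.begin(), lens.end(), std::greater<int>());
      ring_lengths[isamp] = IntegerVector(lens.begin(), lens.end());
      if (count_radius > 0) {
        int nin = 0;
        for (int i = 0; i < s.N; ++i) {
          double d[3] = {s.x[i], s.y[i], s.z[i]};
          s.minim(d);
          if (d[0]*d[0] + d[1]*d[1] + d[2]*d[2] <= count_radius * count_radius) nin++;
        }
        smp_nin.push_back(nin);
      }
      if (store_frames) {
        NumericMatrix fp(s.N, 3);
        for (int i = 0; i < s.N; ++i) {
          fp(i, 0) = s.x[i]; fp(i, 1) = s.y[i]; fp(i, 2) = s.z[i];
        }
        IntegerMatrix fb(s.N, 2);
        int e = 0;
        for (int i = 0; i < s.N; ++i)
          for (int w = 0; w < 2; ++w)
            if (s.nb[i][w] > i) { fb(e, 0) = i + 1; fb(e, 1) = s.nb[i][w] + 1; e++; }
        frames[isamp] = List::create(_["positions"] = fp,
                                     _["bonds"] = fb(Range(0, std::max(e - 1, 0)), _));
      }
      isamp++;
    }
  }

  NumericMatrix outp(s.N, 3), outv(s.N, 3);
  for (int i = 0; i < s.N; ++i) {
    outp(i, 0) = s.x[i]; outp(i, 1) = s.y[i]; outp(i, 2) = s.z[i];
    outv(i, 0) = s.vx[i]; outv(i, 1) = s.vy[i]; outv(i, 2) = s.vz[i];
  }
  int nbonds = 0;
  for (int i = 0; i < s.N; ++i)
    for (int w = 0; w < 2; ++w)
      if (s.nb[i][w] > i) nbonds++;
  IntegerMatrix outb(nbonds, 2);
  int e = 0;
  for (int i = 0; i < s.N; ++i)
    for (int w = 0; w < 2; ++w)
      if (s.nb[i][w] > i) { outb(e, 0) = i + 1; outb(e, 1) = s.nb[i][w] + 1; e++; }

  return List::create(
    _["positions"] = outp, _["velocities"] = outv, _["bonds"] = outb,
    _["wall_radius"] = s.wallR,
    _["attempts"] = s.attempts, _["accepts"] = s.accepts,
    _["sample_step"] = smp_step, _["nr"] = smp_nr,
    _["ring_lengths"] = ring_lengths,
    _["cum_attempts"] = smp_att, _["cum_accepts"] = smp_acc,
    _["kinetic"] = smp_kin, _["potential"] = smp_pot,
    _["n_inside"] = smp_nin, _["frames"] = frames);
}
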