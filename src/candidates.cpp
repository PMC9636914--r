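#include "common.h"
using namespace Rcpp;

// Enumerate reconnection (bond-swap) proposals for a configuration: for every
// unordered bead pair (a, c) with |r_a - r_c| <= rc, not bonded to each other,
// propose breaking (a,b) and (c,d) and forming (a,c) and (b,d), for all four
// choices of b in nb(a), d in nb(c). Proposals whose four beads are not
// distinct, or whose split would create a ring shorter than min_ring_length,
// are excluded. delta_energy is the FENE + bending difference (WCA and wall
// terms do not change under rewiring); +Inf marks a FENE-impossible new bond.
// Brute-force O(N^2) pair scan: this is the reference/analysis path, the MD
// engine repeats the same logic off its neighbor list.
// [[Rcpp::export]]
DataFrame find_candidates_cpp(NumericMatrix pos, IntegerMatrix bonds,
                              List ff, double rc, int min_ring_length) {
  ForcePars p = ff_from_list(ff);
  int N = pos.nrow();
  std::vector<std::array<int, 2>> nb(N, {-1, -1});
  for (int e = 0; e < bonds.nrow(); ++e) {
    int i = bonds(e, 0) - 1, j = bonds(e, 1) - 1;
    for (int w = 0; w < 2; ++w) {
      int a = w == 0 ? i : j, o = w == 0 ? j : i;
      if (nb[a][0] == -1) nb[a][0] = o;
      else if (nb[a][1] == -1) nb[a][1] = o;
      else stop("bead %d has more than two bonds", a + 1);
    }
  }
  // deterministic ring decomposition (lowest unvisited id first)
  std::vector<int> ringid(N, -1), ringpos(N, -1), ringlen;
  for (int start = 0; start < N; ++start) {
    if (ringid[start] != -1 || nb[start][0] < 0) continue;
    int id = ringlen.size();
    int cur = start, prev = -1, q = 0;
    do {
      ringid[cur] = id;
      ringpos[cur] = q++;
      int nxt = (nb[cur][0] == prev) ? nb[cur][1] : nb[cur][0];
      prev = cur;
      cur = nxt;
    } while (cur != start && q <= N);
    if (cur != start) stop("bond graph is not a union of cycles");
    ringlen.push_back(q);
  }
  auto dist2 = [&](int i, int j) {
    double dx = pos(i,0)-pos(j,0), dy = pos(i,1)-pos(j,1), dz = pos(i,2)-pos(j,2);
    return dx*dx + dy*dy + dz*dz;
  };
  auto eb = [&](int i, int j) {
    double r2 = dist2(i, j);
    return fene_energy(r2, p.fene_k, p.fene_r0);
  };
  auto ea = [&](int v, int u, int w) {
    if (u < 0 || w < 0 || p.bend_k == 0.0) return 0.0;
    double a[3] = {pos(v,0)-pos(u,0), pos(v,1)-pos(u,1), pos(v,2)-pos(u,2)};
    double b[3] = {pos(w,0)-pos(v,0), pos(w,1)-pos(v,1), pos(w,2)-pos(v,2)};
    return bend_energy(a, b, p.bend_k);
  };
  std::vector<int> va, vb, vc, vd, vlen1, vlen2;
  std::vector<bool> vsame, vsplit;
  std::vector<double> vde;
  double rc2 = rc * rc;
  for (int a = 0; a < N; ++a) {
    if (nb[a][0] < 0 || nb[a][1] < 0) continue;
    for (int c = a + 1; c < N; ++c) {
      if (nb[c][0] < 0 || nb[c][1] < 0) continue;
      if (nb[a][0] == c || nb[a][1] == c) continue;
      if (dist2(a, c) > rc2) continue;
      for (int wb = 0; wb < 2; ++wb)
        for (int wd = 0; wd < 2; ++wd) {
          int b = nb[a][wb], d = nb[c][wd];
          if (b == d || b == c || d == a) continue;
          bool same = ringid[a] == ringid[c];
          bool split = false;
          int len1 = 0, len2 = 0;
          if (same) {
            int L = ringlen[ringid[a]];
            int sa = (ringpos[b] == (ringpos[a] + 1) % L) ? 1 : 0;
            int sc = (ringpos[d] == (ringpos[c] + 1) % L) ? 1 : 0;
            if (sa != sc) {
              split = true;
              if (sa == 0)
                len1 = ((ringpos[c] - ringpos[a]) % L + L) % L + 1;
              else
                len1 = ((ringpos[a] - ringpos[c]) % L + L) % L + 1;
              len2 = L - len1;
              if (len1 < min_ring_length || len2 < min_ring_length) continue;
            }
          }
          double de = eb(a, c) + eb(b, d) - eb(a, b) - eb(c, d);
          if (R_FINITE(de) && p.bend_k != 0.0) {
            de += ea(a, (nb[a][0] == b ? nb[a][1] : nb[a][0]), c) - ea(a, nb[a][0], nb[a][1]);
            de += ea(b, (nb[b][0] == a ? nb[b][1] : nb[b][0]), d) - ea(b, nb[b][0], nb[b][1]);
            de += ea(c, (nb[c][0] == d ? nb[c][1] : nb[c][0]), a) - ea(c, nb[c][0], nb[c][1]);
            de += ea(d, (nb[d][0] == c ? nb[d][1] : nb[d][0]), b) - ea(d, nb[d][0], nb[d][1]);
          }
          va.push_back(a + 1); vb.push_back(b + 1);
          vc.push_back(c + 1); vd.push_back(d + 1);
          vsame.push_back(same); vsplit.push_back(split);
          vlen1.push_back(len1); vlen2.push_back(len2);
          vde.push_back(de);
        }
    }
  }
  return DataFrame::create(
    _["a"] = va, _["b"] = vb, _["c"] = vc, _["d"] = vd,
    _["delta_energy"] = vde, _["same_ring"] = vsame, _["split"] = vsplit,
    _["len1"] = vlen1, _["len2"] = vlen2);
}
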