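---
title: "Methods: simulating and analysing confined reconnecting ring polymers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing confined reconnecting ring polymers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(reconrings)
```

## The system

`reconrings` simulates a melt of ring polymers confined to a sphere whose
bonds can transiently break and rejoin with a nearby strand ("living" rings,
a minimal model of recombining DNA plasmids or reversibly bonding loop-forming
proteins). The physics question is a topological one: depending on the chain
stiffness $K$ and the confinement radius $R$, the steady state is either a
liquid of many short, segregated, unlinked rings, or a gel-like network of a
few long rings mutually interlocked by Gauss linking — a *topological
gelation*. The package provides the simulator, the topological observables
that diagnose the transition, a mean-field theory that predicts it, and a
simulated elution experiment that makes it vivid.

## Model and force field

Beads of diameter $\sigma$ interact through the standard Kremer–Grest force
field in reduced units ($\sigma = \epsilon = k_BT = m = 1$):

* **Excluded volume**: WCA (purely repulsive Lennard–Jones) between *all* bead
  pairs, cutoff $2^{1/6}\sigma$, shifted to zero at the cutoff. Because the
  WCA term applies regardless of bonding, rewiring bonds never changes it —
  the Metropolis test below only needs bond and bending terms.
* **Bonds**: FENE with $k = 30\,\epsilon/\sigma^2$, $R_0 = 1.5\sigma$
  (attractive logarithm only; the repulsive core is already supplied by the
  WCA term). Equilibrium bond length $\approx 0.97\sigma$.
* **Bending**: Kratky–Porod $U = K(1 - \cos\theta)$ per bond angle. The
  persistence length mapping defaults to $l_p = K\sigma$, the large-$K$
  behaviour of this discrete worm-like chain; it is exposed as a configurable
  function (`persistence_length`) because only the proportionality is fixed
  by the model.
* **Confinement**: a WCA-form repulsion between each bead and the inner
  surface of the sphere, acting on the gap $d = R - |r|$. Smooth, standard,
  and free of corners that could trap beads.

These parameter values are the canonical choice for this model class; all are
configurable through `force_field()`.

The reference system is $N = 1000$ beads compressed to $R = 7\sigma$, i.e.
monomer density $\rho = 3N/(4\pi R^3) \simeq 0.70\sigma^{-3}$ and volume
fraction $\phi = (\pi/6)\rho \simeq 0.37$ (`derived_densities()`).

## Dynamics

The integrator is velocity Verlet with the Grønbech-Jensen/Farago Langevin
discretization: with $b = (1 + \gamma\Delta t/2)^{-1}$,
$a = (1 - \gamma\Delta t/2)b$ and $\beta \sim \mathcal N(0, 2\gamma k_BT
\Delta t)$ per component,

$$r' = r + b\,\Delta t\, v + \tfrac{b\,\Delta t^2}{2} f + \tfrac{b\,\Delta t}{2}\beta,
\qquad
v' = a\,v + \tfrac{\Delta t}{2}(a f + f') + b\,\beta .$$

At $\gamma = 0$ this is plain symplectic velocity Verlet (the NVE limit used
by the energy-conservation tests); at $\gamma = 1$ (the Brownian convention,
so $\tau_B$ = 1 reduced time unit) it samples the canonical ensemble
accurately at the working step $\Delta t = 10^{-3}\tau_B$. Forces come from a
Verlet pair list over a cell grid; the force list uses a 0.3$\sigma$ skin and
the reconnection candidate list a 0.15$\sigma$ skin, with a rebuild whenever
the maximum displacement exceeds half the smaller skin. FENE bond energies in
the Metropolis test are interpolated from a 4096-entry table over $r^2$
(exact form within 2% of the divergence), accurate to $\sim 10^{-6}\,k_BT$.

**Initialization and compression.** The system starts as a single ring of $N$
beads laid out as a spiral wound around a torus (a plain circle for
$N \le 40$), spacing $0.97\sigma$, inscribed in a sphere large enough to hold
it; the wall is then shrunk linearly to the target radius. The default ramp
speed is $0.05\sigma/\tau_B$ — slow on the scale of free-bead diffusion — and
`compress()` warns above $0.2\sigma/\tau_B$. The initial shape is deliberately
irrelevant: compression plus equilibration erases it, which the
reproducibility tests exploit.

## The reconnection move

After every integration step one sweep of bond-swap moves runs:

1. Every bead pair $(a, c)$ with $|r_a - r_c| \le r_c$ (default $1.3\sigma$)
   that is not already bonded is a candidate; for each, all four combinations
   of one bond at each end — $(a,b)$ and $(c,d)$ — are proposed to be rewired
   into $(a,c)$ and $(b,d)$. Four-bead distinctness is required, and an
   intra-ring swap that would create a cycle shorter than `min_ring_length`
   (default 3, the smallest cycle with defined bending angles) is discarded.
   Whether a swap merges two rings, splits one ring, or merely reverses a
   segment of one ring is determined by cycle traversal, not by the rule.
2. Each proposal is accepted with probability
   $\min(1, e^{-\Delta E/k_BT})$, where $\Delta E$ contains exactly the FENE
   terms of the two swapped bonds and the bending terms of the four angles
   centred at $a, b, c, d$ — the only terms a rewiring can change. The unit
   tests verify this local $\Delta E$ against a brute-force total-energy
   difference to $10^{-8}$.
3. Accepted proposals are applied in random order; any proposal touching a
   bead already rewired in the current sweep is skipped, so each bead
   participates in at most one swap per sweep. Testing all proposals against
   the pre-sweep configuration and then resolving conflicts is statistically
   equivalent to visiting them sequentially in random order — non-conflicting
   proposals have disjoint local energy terms — and avoids reshuffling
   $O(10^4)$ proposals at every timestep.

Because the move satisfies detailed balance, reconnection changes the
topology without disturbing thermal equilibrium; the steady-state *ensemble*
is independent of how often moves are attempted. The accepted-swap rate
$\kappa_r$ (reported per $\tau_B$ in the scalar time series) is, in contrast,
purely protocol-dependent: attempting every proximal pair at every step, as
here, yields $\kappa_r$ of order $10^3$–$10^4\tau_B^{-1}$ for the flexible
reference system, dominated by near-zero-$\Delta E$ local swaps. Published
rates for this class of model are far smaller because the attempt schedule
(how many candidate pairs are tested per step) is throttled; that schedule is
not part of the model definition here, and no attempt-fraction knob is
provided because the steady-state observables do not depend on it. The fast
schedule is in fact what makes reduced-size runs reach topological steady
state within desk-scale budgets.

## Topological observables

* **Gauss linking number** (`linking_number`): the double contour integral is
  evaluated *exactly* for polygons as the sum over segment pairs of the
  signed solid angle of the tetrahedron they span (Klenin–Langowski). For
  disjoint curves the result is an integer to better than $10^{-6}$, which
  the tests assert on fixtures (Hopf $\pm1$, Solomon $\pm2$, 3-ring chain)
  against an independent crossing-sign oracle, under random rigid motions and
  discretizations from 32 to 256 vertices.
* **Link network** (`build_link_network`): rings are nodes; an edge marks
  $|Lk| > 0.5$ (a tie at exactly 0.5 counts as unlinked, taking the
  indicator's threshold literally). $N_{Lk}$ is the edge count, $|Lk|$ the
  half-sum of $|Lk(\gamma_i,\gamma_j)|$ over ordered pairs, clusters the
  connected components (via igraph). Ring pairs whose bounding spheres are
  disjoint are provably unlinked and skipped before any integration.
* **Knots** (`knot_invariant`): the ring is reduced by triangle elision
  (a vertex goes when no other segment pierces the triangle spanned with its
  neighbours; coplanar cases are resolved with an exact 2-D overlap test and
  ambiguous geometry conservatively blocks the elision), then the knot
  determinant $|\Delta(-1)|$ is read off a crossing diagram from a random
  projection, retried on degenerate projections. Classification is by
  determinant lookup (1 unknot, 3 trefoil, 5 figure-eight or $5_2$, ...);
  distinct knots sharing a determinant are reported together, and reductions
  retaining more than 100 vertices return "unresolved". Identifying specific
  high-crossing knots is out of scope.

## Mean-field theory

With all of the contour free to reconnect, the number of ways to distribute
$N$ beads into $m$ rings is the Stirling number $\{N, m\} \sim m^N/m!$
(`stirling_second_kind` provides both the exact log-recurrence and this
asymptotic). Adding the bending energy of $m$ circular rings and the
translational entropy gives the free energy implemented in `free_energy()`:

$$\frac{F}{k_BT} = \frac{2 l_p \lambda \pi^2 m^2}{L} + m\log m - m -
m\log(aV),$$

with $\lambda = 5.3$ a shape factor, $a = 0.27$, $V = 4\pi R^3/3$ and $L$ the
**total** contour length ($L = N\sigma$, conserved). The identification of
$L$ with the total length is forced by the derivation: $m$ circular rings of
length $L/m$ have curvature energy $m \times 2\pi^2\lambda l_p/(L/m) =
2\lambda\pi^2 l_p m^2/L$, and the stated validity condition $L \simeq m\,l_p$
(each ring about one persistence length long) only parses this way. It is
also the reading that reproduces the two quantitative signatures: the
minimiser $m^\ast(K)$ then decays with an effective log–log slope of $-0.79$
over $K \in [1,5]$, approaching the asymptotic $\langle N_r\rangle \sim
K^{-1}$ from above (the alternative reading, $L = N/m$, gives $K^{-1/2}$),
and the $c = c^\ast$ construction below crosses near $K \approx 2$ (the
alternative puts it near 1). In the flexible limit $l_p \to 0$ the minimum is
at $m^\ast = aV$ exactly, which the tests use as a closed-form oracle.

**Gelation point.** The overlap concentration of rings of length $L_r$ is
$c^\ast = 3L_r/(4\pi\sigma R_g^3)$ with the ideal-ring gyration radius
$R_g^2 = L_r\sigma/12$ for $K = 0$ and $R_g^2 = (L_r/2l_p)(2l_p)^2/12 =
L_r l_p/6$ for $K \ge 1$ (the two branches are consistent at $l_p =
\sigma/2$; for $0 < K < 1$, where the model is silent, `overlap_concentration`
interpolates linearly in $K$ and flags the result). The concentration *of*
a mean ring is taken as $c = 3L_{\rm mean}(K)/(4\pi R^3)$ — one ring's
monomers spread over the confining sphere; resolving $c$ this way (rather
than as the fixed total density $\rho$, which admits no crossing above
$K = 1$) is what reproduces the expected critical point. `gelation_point()`
brackets the root of $c - c^\ast$ on a $K$ grid and polishes it by bisection;
for the reference parameters it returns $K_c \approx 2.3$.

## Statistical observables

* **Ring-size distribution**: pooled over the last half of the run (the
  steady-state convention everywhere in the package, with a first-half/
  second-half stationarity diagnostic on $N_r$). The power-law exponent of
  $P(L_r) \sim L_r^{-c}$ is estimated by discrete maximum likelihood with the
  normalization truncated to the observed support — histogram-slope fits are
  biased, and truncation keeps $c \le 1$ meaningful on a finite system. The
  lower cutoff is chosen by Kolmogorov–Smirnov minimization. The estimator is
  validated by recovering $c \in \{0.5, 1, 1.5\}$ from synthetic draws.
* **Mixing probability**: for each monomer, the fraction of beads within a
  probe sphere (default radius $2\sigma$, a choice documented with the
  results; the denominator is all beads in the probe except the centre)
  belonging to other rings, averaged over a ring.
* **Radial density** $G(r)$: per ring-length bin, shell counts divided by
  shell volume and normalized by the bin's mean density, so uniform beads
  give $G \equiv 1$ and $\sum G \cdot v_{\rm shell} \cdot \rho_{\rm bin}$
  returns the exact bead count. Radial bins are $0.25\sigma$ wide by default;
  length bins logarithmic.

## The elution (escape) experiment

`permeabilize_and_release()` replaces the smooth wall by immobile WCA sites
on a Fibonacci lattice at the same radius — isotropic, with the pore size
(surface gap between neighbouring sites) set directly by the site spacing —
embeds the sphere in a periodic box (default edge $4R$), resets the stiffness
to `post_K` (default 1, so only the inherited topology differs between
compared systems), optionally freezes reconnection, and records the number of
monomers still inside the sphere, $n(t)$. A liquid of small unlinked rings
drains; a linked network is retained. `fit_escape_curve()` fits
$n(t) = n_0 e^{-(t/\tau)^\beta}$ against a constant-plateau alternative and
selects by residuals.

## What the synthetic conditions do and do not show

All runs in the test suite and acceptance script are *reduced* systems at the
reference density $\rho \approx 0.7\sigma^{-3}$: melts of 60–256 beads
(spheres of radius 2.7–4.4$\sigma$) over $10^2$–$10^3\tau_B$, versus
$N = 1000$, $R = 7\sigma$ and $10^4$–$10^5\tau_B$ for the full study; the
$\kappa_r$ measurement alone runs at the full $N = 1000$ size. The reduced
melts reproduce the mechanisms — power-law ring-size statistics with exponent
close to 1, growth of linking and cluster size with $K$, differential
retention in the elution experiment — but their link networks contain only a
handful of rings, so percolation-style quantities (single-cluster
probability, largest-cluster fraction) are strongly finite-size-affected and
are asserted only directionally. Passing tests therefore demonstrate correct
mechanics and the right qualitative phase behaviour, not quantitative
finite-size-converged phase boundaries. The theory module, by contrast, is
evaluated at full scale (it is analytic).

## Numerical choices and degenerate inputs

* Integer snapping tolerance for linking numbers: $10^{-6}$; curves sharing a
  vertex raise an error (the Gauss integral is singular there).
* Knot projections: random rotations, up to 25 retries on degeneracy
  (near-parallel projected segments, borderline crossing parameters,
  equal-height crossings).
* Free-energy minimization: bracketed scalar search on
  $m \in [1, N/\text{min\_ring\_length}]$, relative tolerance $10^{-8}$;
  boundary minima warn (the flexible reference system has $aV > N/3$, so its
  formal optimum sits at the bracket edge — physically, the min-ring
  constraint binds).
* Metropolis short-circuit: proposals with $\Delta E > 45 + 8K$ are rejected
  without drawing a random number ($e^{-45} \approx 10^{-20}$, far below any
  attainable uniform draw; $8K$ bounds the largest possible bending gain).
* Escape counting uses the minimum-image distance to the sphere centre, so a
  bead sitting exactly in a pore can flicker across the $n(t)$ threshold;
  $n(t)$ is monotone only in expectation.
* Determinism: a run is a pure function of (config, seed). The MD noise
  stream, sweep conflict resolution and knot projections draw from separate
  generators (the engine's own stream vs R's RNG), so analysis randomness
  never perturbs dynamics.

## Known limitations

* No hydrodynamic interactions and no real-unit force field; mapping to
  nm/cP (e.g. $\sigma = 30$ nm, nucleoplasm viscosity) is documentation only.
* $\kappa_r$ is attempt-schedule-dependent (above); only its existence and
  $K$-dependence are physical, not its absolute value.
* Knot classification by determinant cannot separate knots sharing
  $|\Delta(-1)|$.
* The $0 < K < 1$ branch of $R_g^2(K)$ is an interpolation, flagged in
  output.
* Single-site exchange only: finite-segment exchange (as in meiotic
  recombination) is out of scope.
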