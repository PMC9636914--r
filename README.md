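# reconrings

Langevin dynamics of confined **reconnecting ("living") ring polymers** and
the topology analysis needed to study their gelation.

Ring polymers that can transiently break a bond and rejoin with a nearby
strand — DNA plasmids in the presence of recombinases, or reversibly bonding
loop-forming proteins — keep exchanging material while staying in thermal
equilibrium. Confined to a sphere, such a melt has two very different steady
states: a **liquid** of many short, segregated, unlinked rings, and a
**topological gel** in which a few long rings are mechanically interlocked
into a percolating network. Which one you get depends on the chain stiffness
`K` and the confinement radius `R`. This package provides:

* a bead–spring MD engine (WCA + FENE + Kratky–Porod bending, repulsive
  spherical wall, Grønbech-Jensen/Farago Langevin integrator, reduced units
  σ = ε = k<sub>B</sub>T = m = 1) with **bond-swap reconnection moves**
  attempted at every step between segments closer than r<sub>c</sub> = 1.3 σ
  and accepted with the Metropolis probability min(1, e<sup>−ΔE/k<sub>B</sub>T</sup>);
* **topological observables**: exact Gauss linking numbers for polygonal
  curves, Lk(γ<sub>i</sub>, γ<sub>j</sub>) = (1/4π)∮∮ (r₁−r₂)·(dr₁×dr₂)/|r₁−r₂|³,
  the network of linked rings (edges where |Lk| > 0.5) with its clusters, and
  knot detection via the Alexander determinant |Δ(−1)| after KMT-style chain
  reduction;
* a **mean-field theory**: the free energy
  F/k<sub>B</sub>T = 2 l<sub>p</sub> λ π² m²/L + m log m − m − m log(aV)
  (λ = 5.3, a = 0.27, L the total contour length) whose minimiser predicts
  the steady-state ring number ⟨N<sub>r</sub>⟩, plus the overlap-concentration
  construction c = c* that locates the gelation point near K ≈ 2 for the
  reference system (N = 1000 beads, R = 7 σ);
* **observables**: power-law ring-size statistics by discrete maximum
  likelihood, mixing probabilities, radial density profiles G(r), and a
  simulated **elution experiment** in which the sphere is permeabilized into
  a porous mesh and the monomers remaining inside, n(t), are monitored.

## Worked example

A reduced melt (N = 120 beads at the reference density ρ ≈ 0.7 σ⁻³, flexible
chains) run end to end — build one ring, compress, reconnect, analyse:

```r
library(reconrings)

cfg <- simulation_config(n_beads = 120, stiffness = 0,
                         sphere_radius = (3 * 120 / (4 * pi * 0.7))^(1/3),
                         run_length = 150, sample_interval = 15, seed = 42)
st  <- build_initial_ring(cfg)
ff  <- force_field(bending_k = cfg$stiffness)
ip  <- integrator_params(seed = cfg$seed)
st  <- compress(st, compression_schedule(st$box$radius, cfg$sphere_radius,
                                         post_equilibration_time = 10), ff, ip)
rec <- run_with_reconnection(st, cfg, ff, ip, analyze = TRUE)
rec
#> trajectory_record: 11 samples over 150 tauB; Nr 1 -> 6; 617876 accepted swaps
tail(rec$topology, 3)
#>       time nr n_lk abs_lk largest_cluster_fraction single_cluster
#> 9  199.898  2    0      0                    0.500          FALSE
#> 10 214.898  5    0      0                    0.200          FALSE
#> 11 229.898  6    0      0                    0.167          FALSE
size_distribution(rec)$exponent   # P(Lr) ~ Lr^-c, pooled steady-state frames
#> [1] 0.9928093
```

The single ring fragments into a fluctuating population of rings (`nr`), the
link network of each sampled frame is summarised by the number of linked
pairs `n_lk`, the total unsigned linking number `abs_lk` and its cluster
structure, and the pooled steady-state ring sizes follow a power law with
exponent near 1.

The theory module reproduces the phase behaviour at full scale in
milliseconds:

```r
minimize_ring_number(theory_params(stiffness = 2))   # N = 1000, R = 7 defaults
#> phase_point: K = 2, m* = 8.995 rings, <Lr> = 111.2, c = 0.07738, c* = 0.1177 -> liquid
gelation_point()$critical_K
#> [1] 2.337225
```

This flexible-chain (liquid-phase) snapshot drains quickly once the wall is
made porous — a stiff-chain history leaves a linked network that stays
trapped instead:

```r
esc <- permeabilize_and_release(rec$final_state, pore_size = 2.2, post_K = 1,
                                run_length = 100, sample_interval = 10,
                                ip = integrator_params(seed = 7))
round(esc$n_t / 120, 2)  # fraction of monomers still inside the porous sphere
#> [1] 1.00 0.32 0.30 0.22 0.19 0.11 0.06 0.03 0.03 0.03 0.00
```

A thin command-line front end with `simulate / analyze / theory /
observables / escape / fixtures` subcommands ships in `inst/cli/reconrings`.

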