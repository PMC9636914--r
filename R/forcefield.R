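#' Force field parameters
#'
#' The standard Kremer-Grest parameterization for coarse-grained polymers in
#' reduced units: purely repulsive (WCA) Lennard-Jones pairs with cutoff
#' \eqn{2^{1/6}\sigma} shifted to zero at the cutoff, finitely extensible
#' (FENE) bonds with \eqn{k = 30\,\epsilon/\sigma^2} and
#' \eqn{R_0 = 1.5\sigma}, Kratky-Porod bending \eqn{K(1-\cos\theta)} per bond
#' angle, and a WCA-form repulsion between each bead and the inner surface of
#' the confining sphere acting on the gap \eqn{d = R - |r|}.
#'
#' @param bending_k bending constant K (kBT); 0 gives fully flexible chains.
#' @param wca_epsilon,wca_sigma WCA energy and length scales.
#' @param fene_k,fene_r0 FENE spring constant and maximum extension.
#' @param wall_epsilon wall repulsion energy scale.
#' @return an object of class `force_field`.
#' @export
force_field <- function(bending_k = 0, wca_epsilon = 1, wca_sigma = 1,
                        fene_k = 30, fene_r0 = 1.5, wall_epsilon = 1) {
  ff <- list(wca_epsilon = wca_epsilon, wca_sigma = wca_sigma,
             fene_k = fene_k, fene_r0 = fene_r0,
             bending_k = bending_k, wall_epsilon = wall_epsilon)
  stopifnot(ff$wca_epsilon > 0, ff$wca_sigma > 0, ff$fene_k > 0,
            ff$fene_r0 > 0, ff$bending_k >= 0, ff$wall_epsilon > 0)
  class(ff) <- "force_field"
  ff
}

#' @export
print.force_field <- function(x, ...) {
  cat(sprintf(
    "force_field: WCA(eps=%g, sigma=%g) FENE(k=%g, r0=%g) bend K=%g wall eps=%g\n",
    x$wca_epsilon, x$wca_sigma, x$fene_k, x$fene_r0, x$bending_k,
    x$wall_epsilon))
  invisible(x)
}

#' Total potential energy of a configuration
#'
#' Sum of WCA pair energy (all bead pairs, including bonded neighbours),
#' FENE bond energy, bending energy \eqn{K(1-\cos\theta)} per bond angle and
#' wall (or mesh) energy. Fails with an explicit error if any bond is
#' stretched to the FENE divergence (`r >= r0`).
#'
#' @param state a [system_state].
#' @param ff a [force_field()].
#' @param components if `TRUE` return the named breakdown instead of the sum.
#' @return total energy in kBT (or a list of components).
#' @export
total_energy <- function(state, ff = force_field(), components = FALSE) {
  stopifnot(inherits(state, "system_state"))
  e <- energy_components_cpp(state$positions, state$bonds, unclass(ff),
                             state$box)
  if (components) e else e$total
}

#' Bond and bending energy local to a set of beads
#'
#' Returns the sum of all FENE bond terms with at least one endpoint in
#' `beads` plus all bending terms centered at a bead in `beads`. This is the
#' part of the energy a bond-swap move can change: WCA and wall terms depend
#' on positions only and are invariant under rewiring, so the Metropolis
#' energy difference of a proposal is a difference of two `local_energy`
#' evaluations.
#'
#' @param state a [system_state].
#' @param beads integer bead ids (1-based).
#' @param ff a [force_field()].
#' @return energy in kBT.
#' @export
local_energy <- function(state, beads, ff = force_field()) {
  stopifnot(inherits(state, "system_state"), length(beads) >= 1)
  local_bond_bend_cpp(state$positions, state$bonds, as.integer(beads),
                      unclass(ff), state$box)
}
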