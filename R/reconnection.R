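#' Enumerate reconnection (bond-swap) proposals
#'
#' A reconnection move breaks two bonds (a,b) and (c,d) whose designated swap
#' ends satisfy \eqn{|r_a - r_c| \le r_c} and forms (a,c) and (b,d). For each
#' proximal bead pair both bond choices at each end are generated, so one
#' pair yields up to four distinct proposals. Proposals are excluded when the
#' four beads are not distinct, when a and c are already bonded, or when an
#' intra-ring swap would create a cycle shorter than `min_ring_length`.
#' `delta_energy` is the FENE + bending difference between the rewired and
#' current topology (WCA and wall terms do not change under rewiring);
#' `+Inf` marks proposals whose new bond would exceed the FENE extension.
#'
#' @param state a [system_state].
#' @param rc distance cutoff (sigma).
#' @param ff a [force_field()] used for `delta_energy`.
#' @param min_ring_length smallest cycle a split may create.
#' @return data frame with columns a, b, c, d, delta_energy, same_ring,
#'   split, len1, len2 (split lengths; 0 for merges and reversals).
#' @export
find_candidates <- function(state, rc = 1.3, ff = force_field(),
                            min_ring_length = 3) {
  stopifnot(inherits(state, "system_state"))
  find_candidates_cpp(state$positions, state$bonds, unclass(ff), rc,
                      as.integer(min_ring_length))
}

#' Metropolis acceptance for a reconnection move
#'
#' A proposed swap taking the system from configuration \eqn{\omega} to
#' \eqn{\omega'} is accepted with probability
#' \eqn{\min(1, e^{-\Delta E / k_B T})}, i.e. always when the energy
#' difference is negative or zero.
#'
#' @param delta_energy energy difference(s) in kBT.
#' @param temperature kBT (reduced units; default 1).
#' @return `metropolis_accept`: logical vector of draws;
#'   `acceptance_probability`: the acceptance probabilities.
#' @export
acceptance_probability <- function(delta_energy, temperature = 1) {
  pmin(1, exp(-delta_energy / temperature))
}

#' @rdname acceptance_probability
#' @export
metropolis_accept <- function(delta_energy, temperature = 1) {
  runif(length(delta_energy)) < acceptance_probability(delta_energy,
                                                       temperature)
}

#' Apply a bond swap to a state
#'
#' Removes bonds (a,b) and (c,d), adds (a,c) and (b,d). Positions are
#' untouched; the cycle structure updates itself (two rings merge, one ring
#' splits in two, or a ring reverses part of its orientation). A proposal
#' whose old bonds are no longer present is stale and raises an error.
#'
#' @param state a [system_state].
#' @param proposal a list or one-row data frame with fields a, b, c, d.
#' @return the rewired [system_state].
#' @export
apply_swap <- function(state, proposal) {
  p <- as.list(proposal)
  a <- p$a; b <- p$b; cc <- p$c; d <- p$d
  stopifnot(length(unique(c(a, b, cc, d))) == 4)
  bonds <- state$bonds
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  have <- key(bonds[, 1], bonds[, 2])
  i1 <- match(key(a, b), have)
  i2 <- match(key(cc, d), have)
  if (is.na(i1) || is.na(i2))
    stop("stale proposal: bonds (", a, ",", b, ") and (", cc, ",", d,
         ") are not both present")
  bonds[i1, ] <- c(a, cc)
  bonds[i2, ] <- c(b, d)
  state$bonds <- bonds
  state
}

#' One reconnection sweep over a configuration
#'
#' Reference R implementation of the per-step sweep the MD engine performs:
#' all proposals within `rc` are Metropolis-tested against the current
#' configuration, and the accepted ones are applied in random order, skipping
#' any proposal touching a bead already rewired in this sweep (each bead
#' participates in at most one accepted swap per sweep).
#'
#' @inheritParams find_candidates
#' @param temperature kBT.
#' @return list with the updated `state` and a `stats` list
#'   (attempts, accepts).
#' @export
reconnection_sweep <- function(state, rc = 1.3, ff = force_field(),
                               min_ring_length = 3, temperature = 1) {
  cand <- find_candidates(state, rc, ff, min_ring_length)
  if (nrow(cand) == 0)
    return(list(state = state, stats = list(attempts = 0L, accepts = 0L)))
  acc <- which(metropolis_accept(cand$delta_energy, temperature))
  if (length(acc) > 1) acc <- sample(acc)
  touched <- integer(0)
  n_applied <- 0L
  for (i in acc) {
    beads <- c(cand$a[i], cand$b[i], cand$c[i], cand$d[i])
    if (any(beads %in% touched)) next
    state <- apply_swap(state, cand[i, ])
    touched <- c(touched, beads)
    n_applied <- n_applied + 1L
  }
  list(state = state,
       stats = list(attempts = nrow(cand), accepts = n_applied))
}

#' Reconnection statistics
#'
#' Summarises swap bookkeeping: attempts, accepts and the rate
#' \eqn{\kappa_r} = accepted events per tauB over the elapsed time.
#'
#' @param attempts,accepts counters.
#' @param elapsed elapsed time (tauB).
#' @return an object of class `reconnection_stats`.
#' @export
reconnection_stats <- function(attempts, accepts, elapsed) {
  stopifnot(accepts <= attempts, elapsed > 0)
  structure(list(attempts = attempts, accepts = accepts,
                 rate = accepts / elapsed), class = "reconnection_stats")
}

#' @export
print.reconnection_stats <- function(x, ...) {
  cat(sprintf("reconnection_stats: %g attempts, %g accepts, kappa_r = %.4g/tauB\n",
              x$attempts, x$accepts, x$rate))
  invisible(x)
}
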