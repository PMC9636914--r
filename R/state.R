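#' System state
#'
#' A snapshot of the simulation: bead positions and velocities, the bond
#' graph, the elapsed time and the container. The bond graph of a valid
#' simulation state is a disjoint union of cycles (every bead has exactly two
#' bonds); free beads are permitted only for low-level integrator tests.
#'
#' @param positions N x 3 matrix of coordinates (sigma).
#' @param velocities N x 3 matrix (reduced units); defaults to zeros.
#' @param bonds B x 2 integer matrix of 1-based bead pairs.
#' @param time elapsed simulation time (tauB).
#' @param box container descriptor: `sphere_box(radius)` or
#'   `periodic_box(length, mesh)`.
#' @param validate check the cycle invariants (disable for free-bead tests).
#' @return an object of class `system_state`.
#' @export
system_state <- function(positions, velocities = NULL, bonds, time = 0,
                         box = sphere_box(10), validate = TRUE) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (is.null(velocities)) velocities <- matrix(0, nrow(positions), 3)
  velocities <- as.matrix(velocities)
  storage.mode(velocities) <- "double"
  bonds <- matrix(as.integer(bonds), ncol = 2)
  st <- structure(list(positions = positions, velocities = velocities,
                       bonds = bonds, time = time, box = box),
                  class = "system_state")
  if (validate) validate_state(st)
  st
}

#' @rdname system_state
#' @param radius sphere radius (sigma).
#' @export
sphere_box <- function(radius) {
  stopifnot(radius > 0)
  list(type = "sphere", radius = radius)
}

#' @rdname system_state
#' @param length periodic cube edge (sigma).
#' @param mesh optional M x 3 matrix of fixed repulsive sites (a permeabilized
#'   spherical shell in the escape experiments).
#' @param mesh_radius radius of the shell the mesh sites sit on.
#' @export
periodic_box <- function(length, mesh = NULL, mesh_radius = NULL) {
  stopifnot(length > 0)
  list(type = "periodic", length = length, mesh = mesh,
       mesh_radius = mesh_radius)
}

#' Validate the structural invariants of a state
#'
#' Checks that every bead has exactly two bonds, that no bond pairs a bead
#' with itself, that the bond graph decomposes into cycles of length at least
#' `min_ring_length`, and (for spherical confinement) that all beads lie
#' inside the wall.
#'
#' @param state a [system_state].
#' @param min_ring_length smallest legal cycle.
#' @return the state, invisibly; errors describe the violated invariant.
#' @export
validate_state <- function(state, min_ring_length = 3) {
  n <- nrow(state$positions)
  b <- state$bonds
  if (nrow(b) > 0) {
    if (any(b[, 1] == b[, 2])) stop("bond pairs a bead with itself")
    deg <- tabulate(c(b[, 1], b[, 2]), nbins = n)
    if (any(deg != 2))
      stop("bead ", which(deg != 2)[1], " has degree ", deg[deg != 2][1],
           " (every bead of a ring system must have exactly 2 bonds)")
    rs <- extract_rings(state)
    if (any(rs$lengths < min_ring_length))
      stop("ring shorter than min_ring_length found")
    if (sum(rs$lengths) != n) stop("rings do not partition the beads")
  }
  if (identical(state$box$type, "sphere")) {
    r <- sqrt(rowSums(state$positions^2))
    if (any(r >= state$box$radius))
      stop("bead ", which.max(r), " lies outside the confining sphere")
  }
  invisible(state)
}

#' @export
print.system_state <- function(x, ...) {
  rs <- if (nrow(x$bonds) > 0) extract_rings(x) else list(count = 0)
  boxdesc <- if (x$box$type == "sphere")
    sprintf("sphere R=%.3g", x$box$radius)
  else sprintf("periodic L=%.3g%s", x$box$length,
               if (!is.null(x$box$mesh)) sprintf(" + %d mesh sites",
                                                 nrow(x$box$mesh)) else "")
  cat(sprintf("system_state: %d beads, %d bonds, %d ring(s), t = %.4g tauB, %s\n",
              nrow(x$positions), nrow(x$bonds), rs$count, x$time, boxdesc))
  invisible(x)
}

#' Build the initial single-ring configuration
#'
#' The system starts as one closed ring of N beads with consecutive spacing
#' about 0.97 sigma, laid out as a smooth solenoidal curve (a spiral wound
#' around a torus) inscribed in a sphere large enough to hold it without
#' overlaps; small rings (N <= 40) are plain circles. The initial sphere is
#' larger than the target `sphere_radius`; [compress()] shrinks it. The exact
#' initial shape is irrelevant because compression and equilibration erase it.
#' Velocities are drawn from the unit-temperature Maxwell distribution under
#' the configuration seed (centre-of-mass motion removed), so repeated calls
#' with the same config are bit-identical.
#'
#' @param config a [simulation_config()].
#' @param initial_radius optional sphere radius to start from; an error is
#'   raised if the ring cannot be laid out inside it.
#' @param bond_length target consecutive-bead spacing (sigma).
#' @return a [system_state] with one ring of `config$n_beads` beads.
#' @export
build_initial_ring <- function(config, initial_radius = NULL,
                               bond_length = 0.97) {
  n <- config$n_beads
  contour <- n * bond_length
  if (n <= 40) {
    # plain circle with chord length = bond_length
    rad <- bond_length / (2 * sin(pi / n))
    t <- 2 * pi * (seq_len(n) - 1) / n
    pos <- cbind(rad * cos(t), rad * sin(t), 0)
    extent <- rad
  } else {
    # torus spiral: winding spacing ~1.3 sigma at the inner equator keeps
    # neighbouring turns out of WCA contact
    wind <- max(2L, ceiling(sqrt(contour / 1.3)))
    r1 <- 1.3 * wind / (2 * pi)
    R1 <- 2 * r1
    t <- 2 * pi * (seq_len(4 * n) - 1) / (4 * n)   # fine parameter grid
    curve <- cbind((R1 + r1 * cos(wind * t)) * cos(t),
                   (R1 + r1 * cos(wind * t)) * sin(t),
                   r1 * sin(wind * t))
    # resample at equal arc length, then rescale to the target contour
    seglen <- sqrt(rowSums((curve - curve[c(2:nrow(curve), 1), ])^2))
    cum <- cumsum(c(0, seglen[-length(seglen)]))
    total <- sum(seglen)
    want <- total * (seq_len(n) - 1) / n
    idx <- findInterval(want, cum)
    frac <- (want - cum[idx]) / pmax(seglen[idx], 1e-12)
    nxt <- c(2:nrow(curve), 1)
    pos <- curve[idx, , drop = FALSE] +
      frac * (curve[nxt[idx], , drop = FALSE] - curve[idx, , drop = FALSE])
    pos <- pos * contour / total
    extent <- max(sqrt(rowSums(pos^2)))
  }
  need <- extent + 1.5
  if (!is.null(initial_radius)) {
    if (initial_radius < need)
      stop(sprintf(
        "ring of %d beads does not fit in a sphere of radius %.3g (needs %.3g)",
        n, initial_radius, need))
    need <- initial_radius
  }
  vel <- with_seed(config$seed, {
    v <- matrix(rnorm(3 * n), n, 3)
    sweep(v, 2, colMeans(v))           # remove centre-of-mass drift
  })
  bonds <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  system_state(pos, vel, bonds, time = 0, box = sphere_box(need))
}
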