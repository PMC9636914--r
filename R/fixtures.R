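#' Parametric fixtures of known topology
#'
#' Generates discretized closed curves (and one small multi-ring state) whose
#' topological facts are known exactly, used to validate the linking-number
#' and knot machinery: a planar circle (unknot, determinant 1), an unlinked
#' circle pair (Lk = 0), the Hopf link (|Lk| = 1), the Solomon link
#' (the (2,4) torus link, |Lk| = 2), the trefoil (determinant 3), the
#' figure-eight knot (determinant 5), a 3-ring chain catenane (edges A-B and
#' B-C only), and a small melt of unlinked rings.
#'
#' @param name one of `"circle"`, `"unlinked_pair"`, `"hopf"`, `"solomon"`,
#'   `"trefoil"`, `"figure_eight"`, `"chain3"`, `"ring_melt_small"`.
#' @param n_points vertices per curve.
#' @param seed optional seed; when given, a random rigid motion (rotation +
#'   translation) is applied to all curves, which must leave every stored
#'   fact unchanged.
#' @return an object of class `fixture`: `name`, `curves` (list of n x 3
#'   matrices), and `expected` (list of ground-truth facts).
#' @export
make_fixture <- function(name, n_points = 64, seed = NULL) {
  t <- 2 * pi * (seq_len(n_points) - 1) / n_points
  circ <- function(r = 1, center = c(0, 0, 0), plane = "xy") {
    u <- cbind(cos(t), sin(t))
    m <- switch(plane,
                xy = cbind(r * u[, 1], r * u[, 2], 0),
                xz = cbind(r * u[, 1], 0, r * u[, 2]),
                yz = cbind(0, r * u[, 1], r * u[, 2]))
    sweep(m, 2, center, `+`)
  }
  torus_curve <- function(p, q, R0 = 2, r0 = 0.8, phase = 0) {
    cbind((R0 + r0 * cos(q * t + phase)) * cos(p * t),
          (R0 + r0 * cos(q * t + phase)) * sin(p * t),
          r0 * sin(q * t + phase))
  }
  fx <- switch(
    name,
    circle = list(curves = list(circ(2)),
                  expected = list(determinants = 1)),
    unlinked_pair = list(curves = list(circ(1), circ(1, c(5, 0, 0))),
                         expected = list(lk = matrix(c(0, 0, 0, 0), 2),
                                         edges = matrix(0, 0, 2))),
    hopf = list(curves = list(circ(1), circ(1, c(1, 0, 0), "xz")),
                expected = list(abs_lk_pairs = rbind(c(1, 2, 1)),
                                determinants = c(1, 1))),
    solomon = list(curves = list(torus_curve(1, 2),
                                 torus_curve(1, 2, phase = pi)),
                   expected = list(abs_lk_pairs = rbind(c(1, 2, 2)),
                                   determinants = c(1, 1))),
    trefoil = list(curves = list(torus_curve(2, 3, R0 = 2, r0 = 1)),
                   expected = list(determinants = 3)),
    figure_eight = list(
      curves = list(cbind((2 + cos(2 * t)) * cos(3 * t),
                          (2 + cos(2 * t)) * sin(3 * t),
                          sin(4 * t))),
      expected = list(determinants = 5)),
    chain3 = list(
      curves = list(circ(0.8), circ(0.8, c(1.2, 0, 0), "xz"),
                    circ(0.8, c(2.4, 0, 0))),
      expected = list(abs_lk_pairs = rbind(c(1, 2, 1), c(2, 3, 1)),
                      edges = rbind(c(1, 2), c(2, 3)),
                      n_clusters = 1)),
    ring_melt_small = {
      # five unlinked 12-bead rings stacked in a loose column
      t12 <- 2 * pi * (seq_len(12) - 1) / 12
      r12 <- 0.97 / (2 * sin(pi / 12))   # chord length 0.97
      rings <- lapply(0:4, function(k)
        cbind(r12 * cos(t12), r12 * sin(t12), 1.4 * (k - 2)))
      list(curves = rings,
           expected = list(nr = 5, n_lk = 0, n_clusters = 5))
    },
    stop("unknown fixture name: ", name))
  if (!is.null(seed)) {
    fx$curves <- with_seed(seed, {
      rot <- random_rotation_matrix()
      shift <- rnorm(3, sd = 2)
      lapply(fx$curves, function(cv) sweep(cv %*% t(rot), 2, shift, `+`))
    })
  }
  structure(list(name = name, curves = fx$curves, expected = fx$expected),
            class = "fixture")
}

#' Uniform random rotation matrix
#'
#' Drawn from a normalized quaternion; used to verify rigid-motion invariance
#' of the topological invariants.
#'
#' @return a 3 x 3 rotation matrix.
#' @export
random_rotation_matrix <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
    2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
    1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
}

#' Turn fixture curves into a system state
#'
#' Concatenates the fixture's curves into one [system_state] (each curve one
#' ring), so the trajectory-level analysis path can be exercised on known
#' topology.
#'
#' @param fixture a [make_fixture()] result.
#' @param box a box descriptor; default is a sphere comfortably containing
#'   the curves.
#' @return a [system_state].
#' @export
fixture_state <- function(fixture, box = NULL) {
  pos <- do.call(rbind, fixture$curves)
  if (is.null(box)) box <- sphere_box(max(sqrt(rowSums(pos^2))) * 1.5 + 1)
  bonds <- NULL
  off <- 0L
  for (cv in fixture$curves) {
    n <- nrow(cv)
    bonds <- rbind(bonds, cbind(off + seq_len(n),
                                off + c(seq_len(n)[-1], 1L)))
    off <- off + n
  }
  system_state(pos, bonds = bonds, box = box, validate = FALSE)
}
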