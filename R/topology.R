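#' Extract the rings of a configuration
#'
#' Decomposes the degree-2 bond graph into its cycles. The traversal is
#' deterministic: each cycle starts at its lowest unvisited bead id and steps
#' to the lower-id neighbour first, so ring order and orientation are
#' reproducible across platforms.
#'
#' @param state a [system_state] (or a bare B x 2 bond matrix plus `n_beads`).
#' @param n_beads bead count when `state` is a bond matrix.
#' @return an object of class `ring_set`: list of ordered bead-id cycles,
#'   their lengths `Lr`, and the count `Nr`. The rings partition all beads,
#'   so `sum(lengths) == N`.
#' @export
extract_rings <- function(state, n_beads = NULL) {
  if (inherits(state, "system_state")) {
    bonds <- state$bonds
    n <- nrow(state$positions)
  } else {
    bonds <- state
    n <- n_beads
  }
  deg <- tabulate(c(bonds[, 1], bonds[, 2]), nbins = n)
  if (any(deg != 2))
    stop("corrupted state: bead ", which(deg != 2)[1],
         " has degree ", deg[deg != 2][1])
  # adjacency: two neighbours per bead
  nb <- matrix(0L, n, 2)
  slot <- integer(n)
  for (e in seq_len(nrow(bonds))) {
    i <- bonds[e, 1]; j <- bonds[e, 2]
    slot[i] <- slot[i] + 1L; nb[i, slot[i]] <- j
    slot[j] <- slot[j] + 1L; nb[j, slot[j]] <- i
  }
  visited <- logical(n)
  rings <- list()
  for (start in seq_len(n)) {
    if (visited[start]) next
    cyc <- integer(0)
    cur <- start
    prev <- 0L
    repeat {
      visited[cur] <- TRUE
      cyc <- c(cyc, cur)
      nbs <- nb[cur, ]
      nxt <- nbs[nbs != prev]
      if (length(nxt) == 2) nxt <- min(nxt)  # first step: lower id first
      if (nxt == start) break
      prev <- cur
      cur <- nxt
    }
    rings[[length(rings) + 1L]] <- cyc
  }
  structure(list(rings = rings,
                 lengths = lengths(rings),
                 count = length(rings)),
            class = "ring_set")
}

#' @export
print.ring_set <- function(x, ...) {
  cat(sprintf("ring_set: %d ring(s), lengths %s\n", x$count,
              paste(sort(x$lengths, decreasing = TRUE), collapse = " ")))
  invisible(x)
}

#' Gauss linking number of two closed curves
#'
#' Evaluates the Gauss double integral
#' \deqn{Lk(\gamma_i,\gamma_j) = \frac{1}{4\pi}\oint_{\gamma_i}\oint_{\gamma_j}
#'   \frac{r_1 - r_2}{|r_1 - r_2|^3}\cdot(dr_1 \times dr_2)}
#' exactly for polygonal curves, as the sum over all segment pairs of the
#' signed solid angle spanned by the two segments. For disjoint closed curves
#' the result is an integer up to roundoff (< 1e-6 in practice). Curves
#' sharing a vertex make the integral singular and raise an error.
#'
#' @param curve_a,curve_b n x 3 matrices of ordered polygon vertices (closed
#'   implicitly: last connects to first).
#' @return the (real-valued) linking number.
#' @export
linking_number <- function(curve_a, curve_b) {
  linking_number_cpp(as.matrix(curve_a), as.matrix(curve_b))
}

#' Linked-pair indicator
#'
#' Two rings count as linked when `|Lk| > 0.5`; ties at exactly 0.5 count as
#' unlinked.
#'
#' @param lk linking number value(s).
#' @return 0/1 integer vector.
#' @export
linked_pair_indicator <- function(lk) {
  as.integer(abs(lk) > 0.5)
}

#' Build the network of linked rings
#'
#' Computes the Gauss linking number for every unordered ring pair of a
#' configuration (pairs with disjoint bounding spheres are provably unlinked
#' and skipped), applies the linked-pair indicator, and assembles the graph
#' whose nodes are rings and whose edges mark linked pairs. The number of
#' linked pairs \eqn{N_{Lk}} is the edge count; the total unsigned linking
#' number \eqn{|Lk|} is the sum of \eqn{|Lk(\gamma_i,\gamma_j)|} over
#' unordered pairs; clusters are the connected components.
#'
#' @param state a [system_state].
#' @param rings optional [ring_set] (re-extracted otherwise).
#' @return an object of class `link_network`: `lk_matrix`, `edges`, `n_lk`,
#'   `abs_lk`, cluster `membership`, `largest_cluster_fraction`,
#'   `single_cluster`, and the `igraph` object.
#' @export
build_link_network <- function(state, rings = NULL) {
  stopifnot(inherits(state, "system_state"))
  if (is.null(rings)) rings <- extract_rings(state)
  nr <- rings$count
  lk <- linking_matrix_cpp(state$positions, rings$rings)
  chi <- abs(lk) > 0.5
  edges <- which(upper.tri(chi) & chi, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nr)))
  comp <- igraph::components(g)
  structure(list(
    n_rings = nr,
    lengths = rings$lengths,
    lk_matrix = lk,
    edges = unname(edges),
    n_lk = nrow(edges),
    abs_lk = sum(abs(lk[upper.tri(lk)])),
    membership = as.integer(comp$membership),
    n_clusters = comp$no,
    largest_cluster_fraction = max(comp$csize) / nr,
    single_cluster = comp$no == 1L,
    graph = g), class = "link_network")
}

#' @export
print.link_network <- function(x, ...) {
  cat(sprintf(
    "link_network: %d rings, N_Lk = %d linked pairs, |Lk| = %.3g, %d cluster(s)%s\n",
    x$n_rings, x$n_lk, x$abs_lk, x$n_clusters,
    if (x$single_cluster) " [single cluster]" else ""))
  invisible(x)
}

#' Probability that all rings condense into a single linked cluster
#'
#' Fraction of sampled configurations whose link network is one connected
#' component. This observable departs from zero abruptly at the gelation
#' transition.
#'
#' @param networks list of [build_link_network()] results.
#' @return probability in [0, 1].
#' @export
single_cluster_probability <- function(networks) {
  if (length(networks) == 0) stop("no sampled networks")
  mean(vapply(networks, function(n) isTRUE(n$single_cluster), NA))
}

#' Linking probability of a ring
#'
#' Fraction of ring-samples (pooled over configurations) that are linked to
#' at least one other ring. Near the gelation point the fraction of rings in
#' the largest cluster tracks this quantity, and gelation occurs when it is
#' about 1/2.
#'
#' @param networks list of [build_link_network()] results.
#' @return probability in [0, 1].
#' @export
linking_probability <- function(networks) {
  if (length(networks) == 0) stop("no sampled networks")
  linked <- 0
  total <- 0
  for (n in networks) {
    deg <- igraph::degree(n$graph)
    linked <- linked + sum(deg > 0)
    total <- total + n$n_rings
  }
  linked / total
}

knot_label_table <- c(
  "1" = "unknot-compatible",
  "3" = "trefoil-compatible (3_1)",
  "5" = "figure-eight- or 5_2-compatible (4_1, 5_2)",
  "7" = "5_1/6_1/7_2-compatible",
  "9" = "6_2/7_4/9_2-compatible")

#' Knot content of a closed curve
#'
#' Reduces the polygon by repeated triangle elisions that preserve the knot
#' type (a vertex is removed only when no other chain segment pierces the
#' triangle it spans with its neighbours), then computes the knot determinant
#' \eqn{|\Delta(-1)|} from a crossing diagram read off a random projection
#' (re-projected when degenerate). The determinant is an odd integer >= 1 for
#' every knot: 1 for the unknot, 3 for the trefoil, 5 for the figure-eight.
#' Classification is by determinant lookup, so distinct knots sharing a
#' determinant are reported together; curves whose reduction retains more
#' than `max_reduced` vertices, or whose projections stay degenerate, are
#' reported as `"unresolved"`.
#'
#' @param curve n x 3 matrix of ordered polygon vertices, or a [system_state]
#'   together with `ring` (a ring index from [extract_rings()]).
#' @param ring ring index when `curve` is a state.
#' @param seed seed for the projection directions.
#' @param max_reduced resolution limit on the reduced polygon size.
#' @return an object of class `knot_report` with fields `ring`,
#'   `reduced_polygon_size`, `determinant` and `classification`.
#' @export
knot_invariant <- function(curve, ring = NULL, seed = 1, max_reduced = 100) {
  ring_id <- NA_integer_
  if (inherits(curve, "system_state")) {
    rings <- extract_rings(curve)
    stopifnot(!is.null(ring), ring >= 1, ring <= rings$count)
    ring_id <- as.integer(ring)
    curve <- curve$positions[rings$rings[[ring]], , drop = FALSE]
  }
  curve <- as.matrix(curve)
  if (anyDuplicated(round(curve, 12)) > 0)
    stop("polygon has coincident vertices (self-intersecting input)")
  red <- kmt_reduce_cpp(curve)
  out <- list(ring = ring_id, reduced_polygon_size = nrow(red),
              determinant = NA_real_, crossings = NA_integer_,
              classification = "unresolved")
  if (nrow(red) <= max_reduced) {
    dd <- knot_determinant_cpp(red, as.integer(seed))
    if (isTRUE(dd$ok)) {
      out$determinant <- dd$determinant
      out$crossings <- dd$crossings
      key <- as.character(dd$determinant)
      out$classification <- if (key %in% names(knot_label_table))
        knot_label_table[[key]]
      else sprintf("determinant %d (nontrivial knot)", as.integer(dd$determinant))
    }
  }
  structure(out, class = "knot_report")
}

#' @export
print.knot_report <- function(x, ...) {
  cat(sprintf(
    "knot_report:%s reduced to %d vertices, determinant %s -> %s\n",
    if (is.na(x$ring)) "" else sprintf(" ring %d,", x$ring),
    x$reduced_polygon_size,
    ifelse(is.na(x$determinant), "NA", format(x$determinant)),
    x$classification))
  invisible(x)
}
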