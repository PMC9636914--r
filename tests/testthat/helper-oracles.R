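# Independent oracles used across the suite. These deliberately avoid the
# package's computational kernels: energies are summed term by term in plain
# R, and linking numbers are recomputed by counting signed crossings in a
# projection.

# Brute-force total energy (WCA over all pairs incl. bonded, FENE attractive
# part, Kratky-Porod bending, WCA wall on R - |r|).
r_total_energy <- function(state, ff) {
  pos <- state$positions
  n <- nrow(pos)
  wca <- function(r2, eps, sig = 1) {
    if (r2 >= 2^(1 / 3) * sig^2) return(0)
    sr6 <- (sig^2 / r2)^3
    4 * eps * (sr6^2 - sr6) + eps
  }
  e <- 0
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    e <- e + wca(sum((pos[i, ] - pos[j, ])^2), ff$wca_epsilon)
  }
  for (k in seq_len(nrow(state$bonds))) {
    r2 <- sum((pos[state$bonds[k, 1], ] - pos[state$bonds[k, 2], ])^2)
    e <- e - 0.5 * ff$fene_k * ff$fene_r0^2 * log(1 - r2 / ff$fene_r0^2)
  }
  if (nrow(state$bonds) > 0 && ff$bending_k > 0) {
    nb <- lapply(seq_len(n), function(i) {
      b <- state$bonds
      c(b[b[, 1] == i, 2], b[b[, 2] == i, 1])
    })
    for (v in seq_len(n)) {
      if (length(nb[[v]]) != 2) next
      a <- pos[v, ] - pos[nb[[v]][1], ]
      b <- pos[nb[[v]][2], ] - pos[v, ]
      ct <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
      e <- e + ff$bending_k * (1 - min(max(ct, -1), 1))
    }
  }
  if (identical(state$box$type, "sphere")) {
    for (i in seq_len(n)) {
      d <- state$box$radius - sqrt(sum(pos[i, ]^2))
      e <- e + wca(d^2, ff$wall_epsilon)
    }
  }
  e
}

# Linking number as half the sum of signed inter-curve crossings in a generic
# projection (retried under random rotations when degenerate).
lk_crossing_oracle <- function(A, B, tries = 12) {
  cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]
  na <- nrow(A); nb <- nrow(B)
  for (trial in seq_len(tries)) {
    rot <- random_rotation_matrix()
    a <- A %*% t(rot); b <- B %*% t(rot)
    total <- 0
    ok <- TRUE
    for (i in seq_len(na)) {
      i2 <- i %% na + 1
      p <- a[i, 1:2]; r <- a[i2, 1:2] - p
      for (j in seq_len(nb)) {
        j2 <- j %% nb + 1
        q <- b[j, 1:2]; s <- b[j2, 1:2] - q
        den <- cross2(r, s)
        if (abs(den) < 1e-12) next
        tt <- cross2(q - p, s) / den
        uu <- cross2(q - p, r) / den
        eps <- 1e-9
        near <- function(x) abs(x) < eps || abs(x - 1) < eps
        if ((near(tt) && uu > -eps && uu < 1 + eps) ||
            (near(uu) && tt > -eps && tt < 1 + eps)) { ok <- FALSE; break }
        if (tt <= eps || tt >= 1 - eps || uu <= eps || uu >= 1 - eps) next
        z1 <- a[i, 3] + tt * (a[i2, 3] - a[i, 3])
        z2 <- b[j, 3] + uu * (b[j2, 3] - b[j, 3])
        total <- total + if (z1 > z2) sign(den) else -sign(den)
      }
      if (!ok) break
    }
    if (ok) return(total / 2)
  }
  stop("no generic projection found")
}

# Small equilibrated melt at monomer density ~0.7 used by several tests.
make_melt <- function(n_beads = 60, stiffness = 0, seed = 42,
                      run_length = 30, equil = 10) {
  radius <- (3 * n_beads / (4 * pi * 0.7))^(1 / 3)
  cfg <- simulation_config(n_beads = n_beads, stiffness = stiffness,
                           sphere_radius = radius, run_length = run_length,
                           sample_interval = 5, seed = seed)
  st <- build_initial_ring(cfg)
  ff <- force_field(bending_k = stiffness)
  ip <- integrator_params(seed = seed)
  st <- compress(st, compression_schedule(st$box$radius, radius,
                                          post_equilibration_time = equil),
                 ff, ip)
  list(state = st, config = cfg, ff = ff, ip = ip)
}
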