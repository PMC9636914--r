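test_that("size distribution normalizes and handles degenerate input", {
  # monodisperse sample: delta histogram
  sd1 <- size_distribution(rep(12L, 200))
  expect_true(is.na(sd1$exponent))   # no power law in a delta distribution
  expect_equal(sd1$histogram$L, 12)
  expect_equal(sd1$histogram$p, 1)
  expect_equal(sum(sd1$histogram$p), 1)
  expect_error(size_distribution(integer(0)), "no ring lengths")
  # histogram always normalizes over its support
  set.seed(1)
  sd2 <- size_distribution(sample(3:30, 500, replace = TRUE))
  expect_equal(sum(sd2$histogram$p), 1)
})

test_that("the power-law MLE recovers generated exponents", {
  # draws from P(L) ~ L^-c on [3, 300], c in {0.5, 1, 1.5}
  draw <- function(cc, n) {
    support <- 3:300
    sample(support, n, replace = TRUE, prob = support^(-cc))
  }
  set.seed(7)
  for (cc in c(0.5, 1, 1.5)) {
    fit <- fit_powerlaw(draw(cc, 1e4), lmin = 3)
    expect_equal(fit$exponent, cc, tolerance = 0.05)
  }
  # KS-based lmin selection finds the scaling region of a shifted sample
  set.seed(8)
  mixed <- c(sample(3:5, 3000, replace = TRUE), draw(1, 5000))
  fit <- fit_powerlaw(mixed)
  expect_gte(fit$lmin, 3)
  expect_lt(fit$ks, 0.1)
})

test_that("mixing probability distinguishes lone and interpenetrating rings", {
  # a single ring alone: 0 by definition
  ring <- build_initial_ring(simulation_config(n_beads = 12, sphere_radius = 3,
                                               run_length = 1))
  mx <- mixing_probability(ring, probe_radius = 2)
  expect_equal(mx$mixing, 0)
  expect_false(mx$no_neighbours)

  # two uniformly interleaved rings: foreign fraction ~ their bead share
  n <- 40
  t <- 2 * pi * (seq_len(n) - 1) / n
  a <- cbind(3 * cos(t), 3 * sin(t), 0)
  b <- cbind(3 * cos(t + pi / n), 3 * sin(t + pi / n), 0)  # offset interleave
  st <- system_state(rbind(a, b),
                     bonds = rbind(cbind(1:n, c(2:n, 1)),
                                   n + cbind(1:n, c(2:n, 1))),
                     box = sphere_box(10), validate = FALSE)
  mx2 <- mixing_probability(st, probe_radius = 2)
  expect_equal(nrow(mx2), 2)
  expect_equal(mx2$mixing, c(0.5, 0.5), tolerance = 0.08)

  # ring with no neighbours within the probe: flagged, mixing 0
  lone <- system_state(rbind(a, sweep(b, 2, c(100, 0, 0), `+`)),
                       bonds = rbind(cbind(1:n, c(2:n, 1)),
                                     n + cbind(1:n, c(2:n, 1))),
                       box = sphere_box(200), validate = FALSE)
  mx3 <- mixing_probability(lone, ring = 1, probe_radius = 0.2)
  expect_true(mx3$no_neighbours)
  expect_equal(mx3$mixing, 0)
})

test_that("radial density normalizes to 1 for uniform beads and conserves counts", {
  set.seed(3)
  # uniform beads in the sphere, arranged as many small rings
  R <- 6
  n <- 3000
  u <- matrix(rnorm(n * 3), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * R * runif(n)^(1 / 3)
  bonds <- do.call(rbind, lapply(seq(1, n - 2, by = 3), function(i)
    rbind(c(i, i + 1), c(i + 1, i + 2), c(i + 2, i))))
  st <- system_state(u, bonds = bonds, box = sphere_box(R + 0.01),
                     validate = FALSE)
  g <- radial_density(st, r_bin = 1, length_breaks = c(2, 4))
  # G ~ 1 in shells with decent statistics (skip the tiny innermost shell)
  inner <- g$r > 1.5 & g$r < R
  expect_true(all(abs(g$G[inner] - 1) < 0.25))
  # bead-count recovery: sum G x shell volume x bin density = total beads
  vtot <- sum(unique(g[, c("r", "shell_volume")])$shell_volume)
  recovered <- sum(g$G * g$shell_volume *
                   tapply(g$count, g$length_bin, sum)[g$length_bin] / vtot)
  expect_equal(recovered, n, tolerance = 1e-9)

  # all beads at the wall: G peaks in the outermost shell
  t12 <- 2 * pi * (0:11) / 12
  shell <- system_state(cbind(5.8 * cos(t12), 5.8 * sin(t12), 0),
                        bonds = cbind(1:12, c(2:12, 1)),
                        box = sphere_box(6), validate = FALSE)
  g2 <- radial_density(shell, r_bin = 1, length_breaks = c(11, 13), radius = 6)
  expect_equal(g2$r[which.max(g2$G)], 5.5)
})

test_that("escape experiments start full and respect the pore gate", {
  m <- make_melt(60, seed = 10, run_length = 30)
  rec <- run_with_reconnection(m$state, m$config, m$ff, m$ip)
  # pore below the bead diameter: warned, and nothing escapes
  expect_warning(
    esc0 <- permeabilize_and_release(rec$final_state, pore_size = 0.5,
                                     run_length = 10, sample_interval = 2,
                                     ip = integrator_params(seed = 2)),
    "nothing can escape")
  expect_equal(esc0$n_t[1], 60)
  # soft potentials allow rare pore crossings and boundary flicker: ~ N stays
  expect_true(all(esc0$n_t >= 0.9 * 60))
  # wide pores: the liquid leaks out
  esc1 <- permeabilize_and_release(rec$final_state, pore_size = 3,
                                   run_length = 60, sample_interval = 5,
                                   ip = integrator_params(seed = 2))
  expect_equal(esc1$n_t[1], 60)
  expect_lt(tail(esc1$n_t, 1), 30)
})

test_that("escape-curve fits recover stretched exponentials and plateaus", {
  t <- seq(0, 500, by = 5)
  # exact stretched exponential, beta = 0.5
  n_t <- 1000 * exp(-(t / 80)^0.5)
  fit <- fit_escape_curve(t, n_t)
  expect_equal(fit$model, "stretched")
  expect_equal(fit$beta, 0.5, tolerance = 0.05)
  expect_equal(fit$tau, 80, tolerance = 0.05 * 80)
  # pure exponential: beta ~ 1
  fit1 <- fit_escape_curve(t, 1000 * exp(-t / 100))
  expect_equal(fit1$beta, 1, tolerance = 0.02)
  # constant series: plateau model, fraction = constant / n0
  fitc <- fit_escape_curve(t, rep(700, length(t)))
  expect_equal(fitc$model, "plateau")
  expect_equal(fitc$plateau_fraction, 1)
  # pathological non-monotone input is flagged
  fitx <- fit_escape_curve(t[1:20], 500 + 300 * sin(t[1:20]))
  expect_false(fitx$reliable)
})
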