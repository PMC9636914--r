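test_that("gamma = 0 reduces to ballistic motion for a free bead", {
  st <- system_state(matrix(0, 1, 3), matrix(c(1, -0.5, 0.25), 1, 3),
                     bonds = matrix(integer(0), 0, 2),
                     box = sphere_box(50), validate = FALSE)
  st2 <- md_step(st, force_field(0), integrator_params(friction = 0), 100)
  expect_equal(st2$positions[1, ], c(1, -0.5, 0.25) * 0.1, tolerance = 1e-12)
  expect_equal(st2$time, 0.1)
})

test_that("NVE energy drift of an isolated ring stays below 1e-3 relative", {
  cfg <- simulation_config(n_beads = 30, sphere_radius = 6, run_length = 1,
                           seed = 2)
  st <- build_initial_ring(cfg)
  ff <- force_field(bending_k = 2)
  res <- reconrings:::run_engine(st, ff, integrator_params(friction = 0),
                                 10000, sample_every = 500)
  etot <- res$raw$kinetic + res$raw$potential
  expect_lt((max(etot) - min(etot)) / abs(mean(etot)), 1e-3)
})

test_that("the Langevin thermostat equilibrates to kT = 1", {
  # free bead: mean kinetic energy 3/2 kT within 3 SE
  st <- system_state(matrix(0, 1, 3), matrix(0, 1, 3),
                     matrix(integer(0), 0, 2), box = sphere_box(50),
                     validate = FALSE)
  res <- reconrings:::run_engine(st, force_field(0),
                                 integrator_params(seed = 9), 200000,
                                 sample_every = 200)
  kin <- res$raw$kinetic
  se <- sd(kin) / sqrt(length(kin))
  expect_lt(abs(mean(kin) - 1.5), 3 * se + 0.02)

  # interacting ring: kinetic temperature of 3N dof
  m <- make_melt(40, seed = 21, equil = 0)
  res2 <- reconrings:::run_engine(m$state, m$ff, integrator_params(seed = 3),
                                  50000, sample_every = 100)
  temp <- mean(res2$raw$kinetic) / (1.5 * 40)
  se2 <- sd(res2$raw$kinetic / 60) / sqrt(length(res2$raw$kinetic))
  expect_lt(abs(temp - 1), 3 * se2 + 0.02)
})

test_that("compression contains the beads and validates its schedule", {
  cfg <- simulation_config(n_beads = 200, sphere_radius = 5, run_length = 1,
                           seed = 4)
  st <- build_initial_ring(cfg)
  expect_gte(st$box$radius, 12 - 6)  # starts dilute
  sched <- compression_schedule(st$box$radius, 5,
                                post_equilibration_time = 5)
  st2 <- compress(st, sched, force_field(0), integrator_params(seed = 4))
  expect_equal(st2$box$radius, 5)
  expect_lt(max(sqrt(rowSums(st2$positions^2))), 5)
  expect_equal(nrow(st2$bonds), 200)          # topology untouched

  # no-op ramp: equal radii is pure equilibration
  sched0 <- compression_schedule(5, 5, post_equilibration_time = 1)
  expect_equal(sched0$compression_time, 0)
  st3 <- compress(st2, sched0, force_field(0), integrator_params(seed = 4))
  expect_equal(st3$box$radius, 5)

  # too-fast ramp triggers the diagnostic
  fast <- compression_schedule(10, 5, compression_time = 1,
                               post_equilibration_time = 0)
  stf <- build_initial_ring(simulation_config(n_beads = 30, sphere_radius = 5,
                                              run_length = 1))
  expect_warning(compress(stf, fast, force_field(0),
                          integrator_params(seed = 1)), "too fast")

  expect_error(compression_schedule(4, 5))    # must shrink
})

test_that("reconnection runs conserve beads and sample on schedule", {
  m <- make_melt(60, seed = 42)
  rec <- run_with_reconnection(m$state, m$config, m$ff, m$ip)
  # sample times are exactly {t0, t0 + dt_s, ...}
  expect_equal(diff(rec$times), rep(m$config$sample_interval,
                                    length(rec$times) - 1))
  # N = sum Lr at every sample
  expect_true(all(vapply(rec$ring_lengths, sum, 0) == 60))
  expect_true(all(rec$nr == lengths(rec$ring_lengths)))
  # reconnection disabled: topology frozen
  rec0 <- run_with_reconnection(m$state, m$config, m$ff, m$ip,
                                reconnect = FALSE)
  expect_true(all(rec0$nr == 1))
  expect_equal(tail(rec0$accepts, 1), 0)
})

test_that("identical seeds and config give bit-identical trajectories", {
  m <- make_melt(40, seed = 17, run_length = 10)
  r1 <- run_with_reconnection(m$state, m$config, m$ff, m$ip)
  r2 <- run_with_reconnection(m$state, m$config, m$ff, m$ip)
  expect_identical(r1$final_state$positions, r2$final_state$positions)
  expect_identical(r1$final_state$bonds, r2$final_state$bonds)
  expect_identical(r1$accepts, r2$accepts)
})
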