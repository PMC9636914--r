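test_that("initial ring construction gives one cycle with the right geometry", {
  cfg <- simulation_config(n_beads = 1000, sphere_radius = 7, run_length = 1)
  st <- build_initial_ring(cfg)
  expect_equal(nrow(st$positions), 1000)
  expect_equal(nrow(st$bonds), 1000)
  rs <- extract_rings(st)
  expect_equal(rs$count, 1)
  expect_equal(rs$lengths, 1000)
  # consecutive spacing ~ 0.97 sigma
  nxt <- c(2:1000, 1)
  bl <- sqrt(rowSums((st$positions - st$positions[nxt, ])^2))
  expect_true(all(abs(bl - 0.97) < 0.03))
  # fits inside its (initially large) sphere
  expect_lt(max(sqrt(rowSums(st$positions^2))), st$box$radius)

  # smallest legal ring: a triangle
  cfg3 <- simulation_config(n_beads = 3, sphere_radius = 2, run_length = 1)
  st3 <- build_initial_ring(cfg3)
  expect_equal(extract_rings(st3)$lengths, 3)
  bl3 <- sqrt(sum((st3$positions[1, ] - st3$positions[2, ])^2))
  expect_equal(bl3, 0.97, tolerance = 1e-12)

  # determinism under a fixed seed
  cfg50 <- simulation_config(n_beads = 50, sphere_radius = 3, run_length = 1,
                             seed = 7)
  expect_identical(build_initial_ring(cfg50), build_initial_ring(cfg50))

  # explicit failure when the ring cannot fit
  expect_error(build_initial_ring(cfg, initial_radius = 3), "does not fit")
})

test_that("derived densities reproduce the reference system values", {
  dd <- derived_densities(simulation_config(n_beads = 1000, sphere_radius = 7,
                                            run_length = 1))
  expect_equal(dd$monomer_density, 3 * 1000 / (4 * pi * 343))
  # agreement with the printed round-offs (rho ~= 0.70, phi ~= 0.37)
  expect_equal(dd$monomer_density, 0.70, tolerance = 0.02)
  expect_equal(dd$volume_fraction, 0.37, tolerance = 0.02)
  # empty system
  dd0 <- derived_densities(list(n_beads = 0, sphere_radius = 7))
  expect_equal(dd0$monomer_density, 0)
  expect_equal(dd0$volume_fraction, 0)
})

test_that("total energy matches closed forms and the brute-force oracle", {
  ff <- force_field(bending_k = 1)
  # two beads exactly at the WCA cutoff: zero pair energy
  st <- system_state(rbind(c(0, 0, 0), c(2^(1 / 6), 0, 0)),
                     bonds = matrix(integer(0), 0, 2),
                     box = sphere_box(10), validate = FALSE)
  expect_equal(total_energy(st, ff, components = TRUE)$wca, 0)

  # three collinear bonded beads: zero bending term at any K
  st3 <- system_state(rbind(c(-0.97, 0, 0), c(0, 0, 0), c(0.97, 0, 0)),
                      bonds = rbind(c(1, 2), c(2, 3)),
                      box = sphere_box(10), validate = FALSE)
  e3 <- total_energy(st3, force_field(bending_k = 5), components = TRUE)
  expect_equal(e3$bend, 0)

  # regular 10-gon at K = 1: bending energy 10 (1 - cos(2 pi / 10))
  t10 <- 2 * pi * (0:9) / 10
  b <- 0.97
  rad <- b / (2 * sin(pi / 10))
  st10 <- system_state(cbind(rad * cos(t10), rad * sin(t10), 0),
                       bonds = cbind(1:10, c(2:10, 1)),
                       box = sphere_box(10), validate = FALSE)
  e10 <- total_energy(st10, force_field(bending_k = 1), components = TRUE)
  expect_equal(e10$bend, 10 * (1 - cos(2 * pi / 10)), tolerance = 1e-12)

  # full oracle on a small random melt state
  m <- make_melt(30, stiffness = 2, seed = 3, equil = 2)
  expect_equal(total_energy(m$state, m$ff),
               r_total_energy(m$state, m$ff), tolerance = 1e-9)

  # FENE overextension is an explicit failure
  stbad <- system_state(rbind(c(0, 0, 0), c(1.6, 0, 0), c(0.8, 0.5, 0)),
                        bonds = rbind(c(1, 2), c(2, 3), c(3, 1)),
                        box = sphere_box(10), validate = FALSE)
  expect_error(total_energy(stbad, ff), "FENE")
})

test_that("total energy is invariant under global rotation", {
  m <- make_melt(40, stiffness = 1.5, seed = 11, equil = 2)
  e0 <- total_energy(m$state, m$ff)
  set.seed(5)
  for (rep in 1:3) {
    rot <- random_rotation_matrix()
    st2 <- m$state
    st2$positions <- m$state$positions %*% t(rot)
    expect_equal(total_energy(st2, m$ff), e0, tolerance = 1e-9)
  }
})

test_that("local energy is complete and consistent with term counting", {
  m <- make_melt(40, stiffness = 2, seed = 13, equil = 2)
  ec <- total_energy(m$state, m$ff, components = TRUE)
  # all beads: the whole bond + bending energy
  expect_equal(local_energy(m$state, 1:40, m$ff), ec$fene + ec$bend,
               tolerance = 1e-12)
  # summed over singletons, each bond is counted twice and each angle once
  s <- sum(vapply(1:40, function(i) local_energy(m$state, i, m$ff), 0))
  expect_equal(s, 2 * ec$fene + ec$bend, tolerance = 1e-10)
  # K = 0: an interior bead of a straight trimer contributes no bending
  st3 <- system_state(rbind(c(-0.97, 0, 0), c(0, 0, 0), c(0.97, 0, 0)),
                      bonds = rbind(c(1, 2), c(2, 3)),
                      box = sphere_box(10), validate = FALSE)
  e_k0 <- local_bond_bend_cpp(st3$positions, st3$bonds, 2L,
                              unclass(force_field(bending_k = 0)), st3$box)
  e_bonds <- local_bond_bend_cpp(st3$positions, st3$bonds, 2L,
                                 unclass(force_field(bending_k = 5)), st3$box)
  expect_equal(e_k0, e_bonds)  # collinear: bending zero at any K
})

test_that("config invariants are enforced and files round-trip", {
  expect_error(simulation_config(n_beads = 2, run_length = 1))
  expect_error(simulation_config(timestep = 0.02, run_length = 1))
  expect_error(simulation_config(sphere_radius = -1, run_length = 1))
  expect_warning(simulation_config(reconnection_cutoff = 1.6, run_length = 1),
                 "FENE")
  cfg <- simulation_config(n_beads = 120, stiffness = 2.5, sphere_radius = 3.5,
                           run_length = 50, seed = 9)
  path <- withr::local_tempfile(fileext = ".txt")
  write_config(cfg, path)
  expect_equal(read_config(path), cfg)
  writeLines("nonsense = 1", path)
  expect_error(read_config(path), "unknown config key")
})
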