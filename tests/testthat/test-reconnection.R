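test_that("candidate search matches a brute-force scan and the distance gate", {
  # two parallel bonds at separation 1.0 < rc: proposals for each end pairing
  st <- system_state(rbind(c(0, 0, 0), c(0.97, 0, 0), c(1.94, 0, 0),
                           c(0, 1, 0), c(0.97, 1, 0), c(1.94, 1, 0)),
                     bonds = rbind(c(1, 2), c(2, 3), c(3, 1),
                                   c(4, 5), c(5, 6), c(6, 4)),
                     box = sphere_box(10), validate = FALSE)
  cand <- find_candidates(st, rc = 1.3)
  # every vertical pair (1,4), (2,5), (3,6) is within rc; diagonal pairs are
  # sqrt(1 + 0.97^2) > 1.3 away
  expect_setequal(unique(paste(cand$a, cand$c)), c("1 4", "2 5", "3 6"))
  # each proximal pair yields 4 proposals (2 bond choices per end)
  expect_equal(nrow(cand), 12)
  # merges of two triangles: all proposals merge, lengths 0 flagged
  expect_true(all(!cand$same_ring))

  # far-apart bonds: no candidates
  far <- system_state(rbind(c(0, 0, 0), c(0.97, 0, 0), c(0.5, 0.8, 0),
                            c(5, 0, 0), c(5.97, 0, 0), c(5.5, 0.8, 0)),
                      bonds = rbind(c(1, 2), c(2, 3), c(3, 1),
                                    c(4, 5), c(5, 6), c(6, 4)),
                      box = sphere_box(10), validate = FALSE)
  expect_equal(nrow(find_candidates(far, rc = 1.3)), 0)

  # bonded neighbours are never candidate swap ends
  ring <- build_initial_ring(simulation_config(n_beads = 12, sphere_radius = 3,
                                               run_length = 1))
  cand12 <- find_candidates(ring, rc = 1.3)
  bonded <- paste(pmin(ring$bonds[, 1], ring$bonds[, 2]),
                  pmax(ring$bonds[, 1], ring$bonds[, 2]))
  expect_false(any(paste(cand12$a, cand12$c) %in% bonded))
  # and min_ring_length exclusions hold
  expect_true(all(!cand12$split |
                  (cand12$len1 >= 3 & cand12$len2 >= 3)))
})

test_that("delta_energy of proposals equals the full-energy difference", {
  m <- make_melt(50, stiffness = 2, seed = 8)
  cand <- find_candidates(m$state, rc = 1.3, ff = m$ff)
  expect_gt(nrow(cand), 0)
  e0 <- total_energy(m$state, m$ff)
  finite <- which(is.finite(cand$delta_energy))
  for (i in head(finite, 8)) {
    st2 <- apply_swap(m$state, cand[i, ])
    expect_equal(total_energy(st2, m$ff) - e0, cand$delta_energy[i],
                 tolerance = 1e-8)
  }
})

test_that("Metropolis acceptance follows min(1, exp(-dE/kT))", {
  expect_equal(acceptance_probability(0), 1)
  expect_equal(acceptance_probability(-1), 1)   # dE < 0: always accepted
  expect_equal(acceptance_probability(1), exp(-1))
  expect_equal(acceptance_probability(2, temperature = 2), exp(-1))
  # detailed balance: forward/backward acceptance ratio is exp(-dE)
  de <- c(0.3, 1.7, 4)
  expect_equal(acceptance_probability(de) / acceptance_probability(-de),
               exp(-de))
  # empirical acceptance at dE = +1 kT over 1e5 trials: e^-1 within 3 SE
  set.seed(2024)
  n <- 1e5
  acc <- mean(metropolis_accept(rep(1, n)))
  se <- sqrt(exp(-1) * (1 - exp(-1)) / n)
  expect_lt(abs(acc - exp(-1)), 3 * se)
  # dE <= 0 always accepted
  expect_true(all(metropolis_accept(rep(-1, 1000))))
  expect_true(all(metropolis_accept(rep(0, 1000))))
})

test_that("apply_swap merges, splits and reverses cycles correctly", {
  # inter-ring swap merges two triangles into one hexagon
  st <- system_state(rbind(c(0, 0, 0), c(0.97, 0, 0), c(0.5, 0.8, 0),
                           c(0, 1.1, 0), c(0.97, 1.1, 0), c(0.5, 1.9, 0)),
                     bonds = rbind(c(1, 2), c(2, 3), c(3, 1),
                                   c(4, 5), c(5, 6), c(6, 4)),
                     box = sphere_box(10), validate = FALSE)
  merged <- apply_swap(st, list(a = 1, b = 2, c = 4, d = 5))
  rs <- extract_rings(merged)
  expect_equal(rs$count, 1)
  expect_equal(rs$lengths, 6)

  # intra-ring swap, antiparallel bond choice: splits into s and L - s
  ring <- build_initial_ring(simulation_config(n_beads = 20, sphere_radius = 4,
                                               run_length = 1))
  # break (2,3) and (9,10); rejoin (3,9)+(2,10): closes 3..9 into a 7-ring
  split <- apply_swap(ring, list(a = 3, b = 2, c = 9, d = 10))
  rs2 <- extract_rings(split)
  expect_equal(sort(rs2$lengths), c(7, 13))

  # the parallel choice (both successors) reverses a segment, one ring stays
  rev <- apply_swap(ring, list(a = 3, b = 4, c = 9, d = 10))
  rs3 <- extract_rings(rev)
  expect_equal(rs3$count, 1)
  expect_equal(rs3$lengths, 20)

  # applying the inverse swap restores the original bond set
  back <- apply_swap(split, list(a = 3, b = 9, c = 2, d = 10))
  key <- function(b) sort(paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2])))
  expect_identical(key(back$bonds), key(ring$bonds))

  # stale proposals are rejected with an error
  expect_error(apply_swap(split, list(a = 3, b = 4, c = 9, d = 10)), "stale")
})

test_that("sweeps preserve the cycle invariants over many steps", {
  m <- make_melt(60, seed = 5, run_length = 10)
  # 1e4 engine steps with a sweep after every step
  res <- reconrings:::run_engine(m$state, m$ff, m$ip, 10000,
                                 sample_every = 1000, reconnect = TRUE,
                                 rc = 1.3, min_ring_length = 3,
                                 store_frames = TRUE)
  expect_gt(res$raw$accepts, 0)
  for (fr in res$raw$frames) {
    deg <- tabulate(c(fr$bonds[, 1], fr$bonds[, 2]), nbins = 60)
    expect_true(all(deg == 2))
    rs <- extract_rings(fr$bonds, n_beads = 60)
    expect_equal(sum(rs$lengths), 60)
    expect_true(all(rs$lengths >= 3))
  }
  # R-level sweep: same invariants, no candidates -> state unchanged
  sparse <- make_melt(12, seed = 6, run_length = 1, equil = 1)
  sw <- reconnection_sweep(sparse$state, rc = 0.2)
  expect_identical(sw$state$bonds, sparse$state$bonds)
  expect_equal(sw$stats$attempts, 0)
})

test_that("reconnection_stats bookkeeping", {
  st <- reconnection_stats(100, 25, elapsed = 50)
  expect_equal(st$rate, 0.5)
  expect_error(reconnection_stats(10, 25, 1))
})
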