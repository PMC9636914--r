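test_that("ring extraction is deterministic and partitions the beads", {
  ring <- build_initial_ring(simulation_config(n_beads = 12, sphere_radius = 3,
                                               run_length = 1))
  rs <- extract_rings(ring)
  expect_equal(rs$count, 1)
  expect_equal(rs$rings[[1]][1:2], c(1L, 2L))  # lowest id, lower neighbour

  # two disjoint triangles
  bonds <- rbind(c(1, 2), c(2, 3), c(3, 1), c(4, 5), c(5, 6), c(6, 4))
  rs2 <- extract_rings(bonds, n_beads = 6)
  expect_equal(rs2$count, 2)
  expect_equal(rs2$lengths, c(3, 3))

  # degree violation is a corrupted-state failure
  expect_error(extract_rings(rbind(c(1, 2), c(2, 3)), n_beads = 3), "degree")
})

test_that("linking numbers reproduce known links and the crossing oracle", {
  # far-separated circles: unlink
  fx0 <- make_fixture("unlinked_pair", 64)
  expect_equal(linking_number(fx0$curves[[1]], fx0$curves[[2]]), 0,
               tolerance = 1e-9)
  # Hopf: |Lk| = 1; Solomon: |Lk| = 2; both within 1e-6 of an integer
  for (nm in c("hopf", "solomon")) {
    fx <- make_fixture(nm, 64)
    lk <- linking_number(fx$curves[[1]], fx$curves[[2]])
    expect_equal(abs(lk), fx$expected$abs_lk_pairs[1, 3], tolerance = 1e-6)
    expect_lt(abs(lk - round(lk)), 1e-6)
    # independent crossing-sign oracle agrees in sign and value
    set.seed(31)
    expect_equal(lk_crossing_oracle(fx$curves[[1]], fx$curves[[2]]), round(lk))
  }
})

test_that("linking number is antisymmetric under orientation reversal", {
  fx <- make_fixture("solomon", 48)
  a <- fx$curves[[1]]; b <- fx$curves[[2]]
  lk <- linking_number(a, b)
  expect_equal(linking_number(a[rev(seq_len(nrow(a))), ], b), -lk,
               tolerance = 1e-9)
  expect_equal(linking_number(a, b[rev(seq_len(nrow(b))), ]), -lk,
               tolerance = 1e-9)
  expect_equal(linking_number(b, a), lk, tolerance = 1e-9)  # symmetric in order
  # shared vertex makes the integral singular
  expect_error(linking_number(a, rbind(b[-1, ], a[1, ])), "share")
})

test_that("invariants hold under rigid motions and refinement", {
  set.seed(99)
  for (n in c(32, 128, 256)) {
    fxh <- make_fixture("hopf", n, seed = sample.int(1e6, 1))
    expect_equal(abs(linking_number(fxh$curves[[1]], fxh$curves[[2]])), 1,
                 tolerance = 1e-6)
  }
  for (n in c(48, 96, 192)) {
    fxt <- make_fixture("trefoil", n, seed = sample.int(1e6, 1))
    expect_equal(knot_invariant(fxt$curves[[1]], seed = 5)$determinant, 3)
  }
})

test_that("the linked-pair indicator follows the 0.5 threshold exactly", {
  expect_equal(linked_pair_indicator(0.49), 0L)
  expect_equal(linked_pair_indicator(0.5), 0L)   # ties count as unlinked
  expect_equal(linked_pair_indicator(-1.0), 1L)
  expect_equal(linked_pair_indicator(c(0.2, -0.51, 2)), c(0L, 1L, 1L))
})

test_that("link networks count edges, |Lk| and clusters correctly", {
  # 3-ring chain: A-B and B-C linked, one 3-node cluster, N_Lk = 2
  net <- build_link_network(fixture_state(make_fixture("chain3", 64)))
  expect_equal(net$n_lk, 2)
  expect_equal(net$abs_lk, 2, tolerance = 1e-6)
  expect_equal(sort(net$edges), sort(rbind(c(1, 2), c(2, 3))))
  expect_equal(net$n_clusters, 1)
  expect_true(net$single_cluster)
  expect_equal(net$largest_cluster_fraction, 1)
  # N_Lk equals the independent indicator sum over the Lk matrix
  expect_equal(net$n_lk,
               sum(linked_pair_indicator(net$lk_matrix[upper.tri(net$lk_matrix)])))

  # Solomon pair contributes |Lk| = 2 through the network path too
  nets <- build_link_network(fixture_state(make_fixture("solomon", 64)))
  expect_equal(nets$abs_lk, 2, tolerance = 1e-6)

  # all unlinked: singletons
  net0 <- build_link_network(fixture_state(make_fixture("ring_melt_small")))
  expect_equal(net0$n_lk, 0)
  expect_equal(net0$abs_lk, 0, tolerance = 1e-6)
  expect_equal(net0$n_clusters, 5)
})

test_that("cluster and linking probabilities count samples correctly", {
  one <- build_link_network(fixture_state(make_fixture("chain3", 48)))
  none <- build_link_network(fixture_state(make_fixture("ring_melt_small")))
  expect_equal(single_cluster_probability(list(one, one)), 1)
  expect_equal(single_cluster_probability(list(none, none)), 0)
  expect_equal(single_cluster_probability(c(rep(list(one), 3),
                                            rep(list(none), 7))), 0.3)
  expect_error(single_cluster_probability(list()), "no sampled")
  # linking probability pools rings over samples
  expect_equal(linking_probability(list(one)), 1)      # all 3 rings linked
  expect_equal(linking_probability(list(none)), 0)
  expect_equal(linking_probability(list(one, none)), 3 / 8)
})

test_that("knot determinants classify the standard fixtures", {
  expect_equal(knot_invariant(make_fixture("circle", 80)$curves[[1]],
                              seed = 3)$determinant, 1)
  kt <- knot_invariant(make_fixture("trefoil", 96)$curves[[1]], seed = 3)
  expect_equal(kt$determinant, 3)
  expect_match(kt$classification, "trefoil")
  k8 <- knot_invariant(make_fixture("figure_eight", 128)$curves[[1]], seed = 3)
  expect_equal(k8$determinant, 5)
  # determinant is odd for every resolved knot fixture
  expect_true(kt$determinant %% 2 == 1 && k8$determinant %% 2 == 1)
  # coincident vertices are rejected
  bad <- make_fixture("circle", 16)$curves[[1]]
  expect_error(knot_invariant(rbind(bad, bad[1, ])), "coincident")
})

test_that("triangle elision preserves the determinant along the reduction", {
  fx <- make_fixture("trefoil", 64)$curves[[1]]
  d_full <- knot_determinant_cpp(fx, 11)$determinant
  red <- kmt_reduce_cpp(fx)
  expect_lt(nrow(red), nrow(fx))
  expect_equal(knot_determinant_cpp(red, 11)$determinant, d_full)
  # partially reduced intermediate (single pass) agrees as well
  red1 <- kmt_reduce_cpp(fx, max_passes = 1)
  expect_equal(knot_determinant_cpp(red1, 11)$determinant, d_full)
})

test_that("disjoint bounding spheres imply unlinked rings (prefilter is safe)", {
  # rings far apart get Lk 0 from the prefilter; verify against direct kernel
  fx <- make_fixture("unlinked_pair", 32)
  st <- fixture_state(fx)
  net <- build_link_network(st)
  expect_equal(net$lk_matrix[1, 2],
               linking_number(fx$curves[[1]], fx$curves[[2]]),
               tolerance = 1e-9)
})

test_that("simulation ring pairs give integer linking numbers", {
  m <- make_melt(60, seed = 12, run_length = 30)
  rec <- run_with_reconnection(m$state, m$config, m$ff, m$ip)
  st <- rec$final_state
  rs <- extract_rings(st)
  if (rs$count >= 2) {
    lk <- linking_matrix_cpp(st$positions, rs$rings)
    off <- lk[upper.tri(lk)]
    expect_true(all(abs(off - round(off)) < 1e-6))
  }
  succeed()
})
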