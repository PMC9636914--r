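test_that("free energy transcribes term by term and vectorizes", {
  p <- theory_params(stiffness = 2, n_beads = 1000, radius = 7)
  m <- c(1, 5.5, 40)
  manual <- 2 * p$lp * p$lam * pi^2 * m^2 / 1000 +
    m * log(m) - m - m * log(p$a * 4 / 3 * pi * 343)
  expect_equal(free_energy(m, p), manual, tolerance = 1e-14)
  # m = 1, aV = e: entropy terms sum to -2 (log 1 = 0)
  pe <- theory_params(lp = 0, radius = (exp(1) / (0.27 * 4 / 3 * pi))^(1 / 3),
                      n_beads = 1000)
  expect_equal(free_energy(1, pe), -2, tolerance = 1e-10)
  expect_error(free_energy(0, p), "positive")
})

test_that("the flexible limit minimizes at m* = aV", {
  # choose a system where aV is inside the bracket [1, N/3]
  p <- theory_params(lp = 0, n_beads = 1000, radius = 5)
  pp <- minimize_ring_number(p)
  expect_equal(pp$m_star, p$a * p$volume, tolerance = 1e-5)
  expect_equal(pp$m_star * pp$l_mean, 1000, tolerance = 1e-8)
  # boundary minimum (aV beyond N/min_ring_length) warns
  expect_warning(minimize_ring_number(theory_params(lp = 0, n_beads = 1000,
                                                    radius = 7)), "boundary")
})

test_that("the predicted ring number falls with stiffness like a power law", {
  ex <- nr_stiffness_exponent(k_range = c(1, 5), n_grid = 21)
  expect_lt(ex$exponent, -0.6)
  expect_gt(ex$exponent, -1.1)
  tab <- ex$table
  # <Nr> decreasing, <Lr> increasing, product exactly N
  expect_true(all(diff(tab$m_star) < 0))
  expect_true(all(diff(tab$l_mean) > 0))
  expect_equal(tab$m_star * tab$l_mean, rep(1000, nrow(tab)), tolerance = 1e-8)
})

test_that("free energy is convex over the searched bracket at defaults", {
  for (K in c(0.5, 1, 3, 5)) {
    p <- theory_params(stiffness = K)
    m <- seq(1, 1000 / 3, length.out = 400)
    f <- free_energy(m, p)
    expect_true(all(diff(diff(f)) > -1e-9))
  }
})

test_that("Stirling numbers: exact recurrence and asymptotics", {
  expect_equal(stirling_second_kind(3, 2), log(3))      # {3,2} = 3 partitions
  expect_equal(stirling_second_kind(4, 2), log(7))
  expect_equal(stirling_second_kind(6, 3), log(90))
  for (n in c(1, 5, 60)) expect_equal(stirling_second_kind(n, 1), 0)
  expect_error(stirling_second_kind(3, 4), "m > n")
  # S(N, m) m! / m^N -> 1: within 1% at N = 200, m = 3
  ratio <- exp(stirling_second_kind(200, 3) -
               stirling_second_kind(200, 3, method = "asymptotic"))
  expect_equal(ratio, 1, tolerance = 0.01)
})

test_that("overlap concentration follows the ideal-ring gyration radius", {
  p <- theory_params(stiffness = 0)
  # K = 0, L = 1200: Rg^2 = 100, c* = 3 x 1200 / (4 pi 1000)
  expect_equal(overlap_concentration(1200, 0, p),
               3 * 1200 / (4 * pi * 1000), tolerance = 1e-12,
               ignore_attr = TRUE)
  # stiff branch: Rg^2 = L lp / 6 doubles when K doubles
  p2 <- theory_params(stiffness = 2)
  rg2 <- function(L, K) (3 * L / (4 * pi *
    unclass(overlap_concentration(L, K, theory_params(stiffness = K)))))^(2 / 3)
  expect_equal(rg2(600, 4) / rg2(600, 2), 2, tolerance = 1e-9,
               ignore_attr = TRUE)
  # c* ~ L^(-1/2): strictly decreasing in L at fixed K >= 1
  L <- seq(50, 900, by = 50)
  cs <- vapply(L, function(l) unclass(overlap_concentration(l, 2, p2)), 0)
  expect_true(all(diff(cs) < 0))
})

test_that("the c = c* crossing sits near K = 2 and is grid-robust", {
  gp <- gelation_point(k_range = c(0.5, 6), n_grid = 40)
  expect_equal(gp$critical_K, 2, tolerance = 0.5 / 2)  # within +-0.5
  # sweep-grid refinement does not move the root
  gp2 <- gelation_point(k_range = c(0.5, 6), n_grid = 200)
  expect_equal(gp$critical_K, gp2$critical_K, tolerance = 1e-3)
  # monotone construction: c rises with K, c* falls
  tab <- gp$table[gp$table$K >= 1, ]
  expect_true(all(diff(tab$c) > 0))
  expect_true(all(diff(tab$c_star) < 0))
  # shrinking R at fixed K moves the system toward the gel regime
  pp7 <- minimize_ring_number(theory_params(stiffness = 1.5, radius = 7))
  pp5 <- minimize_ring_number(theory_params(stiffness = 1.5, radius = 5))
  expect_gt(pp5$c / pp5$c_star, pp7$c / pp7$c_star)
  # no crossing in a gel-only range is reported as such
  expect_message(gpx <- gelation_point(k_range = c(4, 6), n_grid = 10),
                 "no .* transition")
  expect_true(is.na(gpx$critical_K))
})
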