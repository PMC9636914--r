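#' Mean-field theory parameters
#'
#' Parameters of the free energy governing how N beads distribute into m
#' rings inside a sphere of volume \eqn{V = 4\pi R^3/3}:
#' \deqn{F/k_BT = \frac{2 l_p \lambda \pi^2 m^2}{L} + m\log m - m - m\log(aV)}
#' where L is the total contour length (\eqn{L = N\sigma}, conserved by
#' reconnection), \eqn{l_p} the persistence length, \eqn{\lambda} a shape
#' factor of the curved rings and \eqn{a} a numerical factor; the entropic
#' terms descend from the large-N Stirling-number asymptotics
#' \eqn{\{N, m\} \sim m^N/m!} together with ring translational entropy. The
#' bending term is the curvature energy of m rings of mean length L/m, each
#' contributing \eqn{2\pi^2\lambda l_p m / L} (curvature ~ m/L, valid for
#' short rings with \eqn{L \simeq m\, l_p}).
#'
#' @param lam shape factor lambda (default 5.3).
#' @param a numerical factor (default 0.27).
#' @param stiffness bending constant K; sets `lp = lp_map(K)` unless `lp`
#'   is given directly.
#' @param lp persistence length (sigma); overrides `stiffness`.
#' @param n_beads total bead count N.
#' @param radius sphere radius R (sigma).
#' @param min_ring_length smallest ring; bounds the minimization bracket.
#' @param lp_map stiffness-to-persistence-length mapping (default
#'   [persistence_length()], i.e. lp = K sigma).
#' @return an object of class `theory_params`.
#' @export
theory_params <- function(lam = 5.3, a = 0.27, stiffness = NULL, lp = NULL,
                          n_beads = 1000, radius = 7, min_ring_length = 3,
                          lp_map = persistence_length) {
  if (is.null(lp)) {
    if (is.null(stiffness)) stop("give either stiffness or lp")
    lp <- lp_map(stiffness)
  }
  p <- list(lam = lam, a = a, stiffness = stiffness, lp = lp,
            n_beads = n_beads, radius = radius,
            volume = 4 / 3 * pi * radius^3,
            min_ring_length = min_ring_length, lp_map = lp_map)
  stopifnot(p$lam > 0, p$a > 0, p$lp >= 0, p$n_beads > 0, p$radius > 0)
  class(p) <- "theory_params"
  p
}

#' Free energy of m reconnecting rings
#'
#' Evaluates \eqn{F/k_BT = 2 l_p \lambda \pi^2 m^2 / L + m\log m - m -
#' m\log(aV)} with L the total contour length \eqn{N\sigma}. In the flexible
#' limit \eqn{l_p \to 0} the minimum sits at \eqn{m^\ast = aV} exactly.
#'
#' @param m ring count (may be fractional; vectorized).
#' @param params a [theory_params()].
#' @return F in kBT units.
#' @export
free_energy <- function(m, params) {
  stopifnot(inherits(params, "theory_params"))
  if (any(m <= 0)) stop("ring number m must be positive")
  L <- params$n_beads  # total contour length in sigma (bond length ~ sigma)
  2 * params$lp * params$lam * pi^2 * m^2 / L +
    m * log(m) - m - m * log(params$a * params$volume)
}

#' Minimize the free energy over the ring number
#'
#' Continuous minimization of [free_energy()] over
#' \eqn{m \in [1, N/\mathrm{min\_ring\_length}]} by bracketed scalar search
#' (relative tolerance 1e-8). The minimizer predicts the steady-state mean
#' ring number \eqn{\langle N_r\rangle = m^\ast} and mean length
#' \eqn{\langle L_r\rangle = N/m^\ast}; a boundary minimum triggers a
#' warning.
#'
#' @param params a [theory_params()].
#' @return an object of class `phase_point` with `m_star`, `l_mean`, the
#'   mean-ring concentration `c`, the overlap concentration `c_star` and the
#'   `regime` ("liquid" when c < c*, "gel" otherwise).
#' @export
minimize_ring_number <- function(params) {
  stopifnot(inherits(params, "theory_params"))
  upper <- params$n_beads / params$min_ring_length
  opt <- optimize(free_energy, c(1, upper), params = params,
                  tol = 1e-8 * upper)
  m_star <- opt$minimum
  tol <- 1e-4 * upper
  if (m_star - 1 < tol || upper - m_star < tol)
    warning("free-energy minimum at the bracket boundary", call. = FALSE)
  l_mean <- params$n_beads / m_star
  K <- if (is.null(params$stiffness)) NA_real_ else params$stiffness
  conc <- mean_ring_concentration(l_mean, params)
  cstar <- if (is.na(K)) NA_real_ else overlap_concentration(l_mean, K, params)
  structure(list(stiffness = K, m_star = m_star, l_mean = l_mean,
                 c = conc, c_star = cstar,
                 regime = if (!is.na(cstar) && conc > cstar) "gel" else "liquid",
                 free_energy = opt$objective),
            class = "phase_point")
}

#' @export
print.phase_point <- function(x, ...) {
  cat(sprintf(
    "phase_point: K = %s, m* = %.4g rings, <Lr> = %.4g, c = %.4g, c* = %.4g -> %s\n",
    format(x$stiffness), x$m_star, x$l_mean, x$c, x$c_star, x$regime))
  invisible(x)
}

# monomer concentration of a single mean-length ring spread over the sphere
mean_ring_concentration <- function(L, params) {
  3 * L / (4 * pi * params$radius^3)
}

#' Stirling numbers of the second kind (log scale)
#'
#' \eqn{\{N, m\}} counts the ways to distribute N labelled beads into m
#' nonempty rings and supplies the combinatorial entropy of the theory. The
#' exact value follows the standard recurrence
#' \eqn{S(n,m) = m S(n-1,m) + S(n-1,m-1)} evaluated in log space; the
#' large-N asymptotic is \eqn{\{N, m\} \sim m^N/m!}.
#'
#' @param n item count.
#' @param m part count (1 <= m <= n).
#' @param method `"exact"` (recurrence) or `"asymptotic"`.
#' @return log S(n, m).
#' @export
stirling_second_kind <- function(n, m, method = c("exact", "asymptotic")) {
  method <- match.arg(method)
  n <- as.integer(n); m <- as.integer(m)
  if (m > n) stop("m > n: no partition of n items into m nonempty parts")
  if (m < 1 || n < 1) stop("need n >= m >= 1")
  if (method == "asymptotic") return(n * log(m) - lfactorial(m))
  # log-space recurrence over rows; logS[j] = log S(row, j)
  logadd <- function(x, y) {
    if (x == -Inf) return(y)
    if (y == -Inf) return(x)
    mx <- max(x, y)
    mx + log1p(exp(min(x, y) - mx))
  }
  logS <- c(0, rep(-Inf, m))          # row n = 1: S(1,1) = 1
  if (n > 1) for (row in 2:n) {
    newS <- rep(-Inf, m)
    for (j in seq_len(min(row, m))) {
      term1 <- if (logS[j] > -Inf) log(j) + logS[j] else -Inf
      term2 <- if (j > 1) logS[j - 1] else -Inf
      newS[j] <- logadd(term1, term2)
    }
    logS <- newS
  }
  logS[m]
}

#' Overlap concentration of rings of length L
#'
#' \deqn{c^\ast = \frac{3L}{4\pi\sigma R_g^3}}
#' the concentration above which rings of contour length L start to overlap,
#' with the ideal-ring gyration radius \eqn{R_g^2 = L\sigma/12} for fully
#' flexible rings (K = 0) and \eqn{R_g^2 = (L/2l_p)(2l_p)^2/12 = L\,l_p/6}
#' for stiff rings (K >= 1); for 0 < K < 1 the two branches are joined by
#' linear interpolation in K (flagged in the result's attribute).
#'
#' @param L ring contour length (sigma).
#' @param K stiffness.
#' @param params a [theory_params()] (supplies the lp mapping).
#' @return c* in sigma^-3.
#' @export
overlap_concentration <- function(L, K, params = theory_params(stiffness = K)) {
  stopifnot(all(L > 0), all(K >= 0))
  rg2_flex <- L / 12
  lp1 <- params$lp_map(pmax(K, 1))
  rg2_stiff <- L * lp1 / 6
  w <- pmin(pmax(K, 0), 1)
  rg2 <- (1 - w) * rg2_flex + w * rg2_stiff
  cs <- 3 * L / (4 * pi * rg2^1.5)
  attr(cs, "interpolated") <- K > 0 & K < 1
  cs
}

#' Theory sweep over stiffness
#'
#' Tabulates the free-energy prediction over a grid of K: optimal ring
#' number, mean length, mean-ring concentration, overlap concentration and
#' regime.
#'
#' @param k_values stiffness grid.
#' @param ... passed to [theory_params()] (lam, a, n_beads, radius, ...).
#' @return data frame with columns K, m_star, l_mean, c, c_star, regime.
#' @export
theory_table <- function(k_values, ...) {
  rows <- lapply(k_values, function(K) {
    pp <- minimize_ring_number(theory_params(stiffness = K, ...))
    data.frame(K = K, m_star = pp$m_star, l_mean = pp$l_mean,
               c = pp$c, c_star = pp$c_star, regime = pp$regime)
  })
  do.call(rbind, rows)
}

#' Scaling exponent of the predicted ring number with stiffness
#'
#' Regresses \eqn{\log m^\ast} on \eqn{\log K} over a stiffness window; the
#' theory predicts \eqn{\langle N_r\rangle \sim K^{-1}} at large K.
#'
#' @param k_range window of K values.
#' @param n_grid grid points (log-spaced).
#' @param ... passed to [theory_params()].
#' @return list with `exponent` and the underlying `table`.
#' @export
nr_stiffness_exponent <- function(k_range = c(1, 5), n_grid = 21, ...) {
  ks <- exp(seq(log(k_range[1]), log(k_range[2]), length.out = n_grid))
  tab <- theory_table(ks, ...)
  fit <- lm(log(m_star) ~ log(K), data = tab)
  list(exponent = unname(coef(fit)[2]), table = tab)
}

#' Gelation point from the c = c* crossing
#'
#' The mean-ring concentration \eqn{c(K) = 3 L_{mean}(K)/(4\pi R^3)} grows
#' with K (rings get longer) while the overlap concentration
#' \eqn{c^\ast(K)} of those rings falls, so the two curves cross once; the
#' crossing marks the critical stiffness separating the liquid of unlinked
#' rings from the topological gel. The root of \eqn{c - c^\ast} is bracketed
#' on a K grid and polished by bisection ([uniroot()]).
#'
#' @param k_range stiffness sweep.
#' @param n_grid coarse-bracketing grid size.
#' @param tol root tolerance in K.
#' @param ... passed to [theory_params()].
#' @return list with `critical_K` (NA if no crossing in range, with a
#'   message), and the sweep `table`.
#' @export
gelation_point <- function(k_range = c(0.5, 6), n_grid = 40, tol = 1e-4, ...) {
  f <- function(K) {
    pp <- minimize_ring_number(theory_params(stiffness = K, ...))
    pp$c - pp$c_star
  }
  ks <- seq(k_range[1], k_range[2], length.out = n_grid)
  vals <- vapply(ks, f, 0)
  sc <- which(diff(sign(vals)) != 0)
  tab <- theory_table(ks, ...)
  if (length(sc) == 0) {
    message("no liquid/gel transition in the given K range")
    return(list(critical_K = NA_real_, table = tab))
  }
  root <- uniroot(f, c(ks[sc[1]], ks[sc[1] + 1]), tol = tol)
  list(critical_K = root$root, table = tab)
}
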