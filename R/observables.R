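#' Steady-state ring-size distribution
#'
#' Pools ring lengths over a window of a trajectory (default: the second half
#' of the run, the steady-state convention used throughout) and returns the
#' normalized size histogram together with a maximum-likelihood power-law fit
#' \eqn{P(L_r) \sim L_r^{-c}}. A stationarity diagnostic compares the mean
#' ring number of the first and second halves of the window.
#'
#' @param record a `trajectory_record`, or a bare integer vector of pooled
#'   ring lengths.
#' @param steady_window time window `c(from, to)` (tauB); `NULL` uses the
#'   last half of the run.
#' @param fit_range optional `c(lmin, lmax)` restriction for the fit.
#' @param log_bins also return a logarithmically binned histogram (counts per
#'   unit length), convenient for plotting broad distributions.
#' @return list with `lengths` (pooled), `histogram` (data frame with L,
#'   count, p), optionally `log_histogram`, `exponent`, `fit` (full
#'   [fit_powerlaw()] result) and `stationary` (logical diagnostic, NA for
#'   bare vectors).
#' @export
size_distribution <- function(record, steady_window = NULL,
                              fit_range = NULL, log_bins = FALSE) {
  stationary <- NA
  if (inherits(record, "trajectory_record")) {
    times <- record$times
    if (is.null(steady_window))
      steady_window <- c(times[1] + diff(range(times)) / 2, max(times))
    sel <- which(times >= steady_window[1] & times <= steady_window[2])
    if (length(sel) == 0) stop("empty steady-state window")
    lengths <- unlist(record$ring_lengths[sel])
    nr <- record$nr[sel]
    if (length(sel) >= 4) {
      h1 <- nr[seq_len(length(nr) %/% 2)]
      h2 <- nr[-seq_len(length(nr) %/% 2)]
      se <- sqrt(var(nr) / length(nr))
      stationary <- abs(mean(h1) - mean(h2)) <= 2 * max(se, .Machine$double.eps)
    }
  } else {
    lengths <- as.integer(record)
    if (length(lengths) == 0) stop("no ring lengths supplied")
  }
  tab <- table(lengths)
  hist <- data.frame(L = as.integer(names(tab)),
                     count = as.integer(tab))
  hist$p <- hist$count / sum(hist$count)
  fit_lengths <- lengths
  if (!is.null(fit_range))
    fit_lengths <- lengths[lengths >= fit_range[1] & lengths <= fit_range[2]]
  # a degenerate (e.g. monodisperse) sample has no power-law exponent
  fit <- if (length(unique(fit_lengths)) >= 3) fit_powerlaw(fit_lengths)
  else NULL
  out <- list(lengths = lengths, histogram = hist,
              exponent = if (is.null(fit)) NA_real_ else fit$exponent,
              fit = fit, stationary = stationary)
  if (log_bins) {
    edges <- unique(round(exp(seq(log(max(min(lengths) - 0.5, 0.5)),
                                  log(max(lengths) + 0.5),
                                  length.out = 13))))
    if (length(edges) > 1) {
      cuts <- cut(lengths, breaks = edges, include.lowest = TRUE)
      cnt <- as.integer(table(cuts))
      out$log_histogram <- data.frame(
        L_mid = sqrt(edges[-length(edges)] * edges[-1]),
        count = cnt,
        density = cnt / diff(edges) / length(lengths))
    }
  }
  out
}

#' Discrete power-law fit by maximum likelihood
#'
#' Fits \eqn{P(L) \propto L^{-c}} on the integer support
#' `[lmin, max(lengths)]` by maximizing the truncated-zeta likelihood
#' (histogram-slope fitting is biased, so the estimate comes from the raw
#' lengths). When `lmin` is `NULL` it is chosen by minimizing the
#' Kolmogorov-Smirnov distance between the fitted and empirical distribution
#' over candidate cutoffs, following the standard discrete power-law recipe.
#' The truncated normalization keeps exponents c <= 1 meaningful, as needed
#' for the \eqn{P(L_r) \sim 1/L_r} distributions of reconnecting rings.
#'
#' @param lengths integer sample.
#' @param lmin lower cutoff of the fit (NULL = choose by KS).
#' @return list with `exponent`, `lmin`, `ks`, `n_tail` (sample size at or
#'   above lmin).
#' @export
fit_powerlaw <- function(lengths, lmin = NULL) {
  lengths <- as.integer(lengths[lengths >= 1])
  stopifnot(length(lengths) >= 2)
  lmax <- max(lengths)
  fit_at <- function(lm) {
    tail_len <- lengths[lengths >= lm]
    if (length(tail_len) < 2 || length(unique(tail_len)) < 2) return(NULL)
    support <- lm:lmax
    nll <- function(cc) {
      logz <- log(sum(support^(-cc)))
      cc * sum(log(tail_len)) + length(tail_len) * logz
    }
    opt <- optimize(nll, c(0.01, 6))
    cc <- opt$minimum
    # KS distance on the tail
    pz <- support^(-cc) / sum(support^(-cc))
    cdf_fit <- cumsum(pz)
    emp <- vapply(support, function(s) mean(tail_len <= s), 0)
    list(exponent = cc, lmin = lm, ks = max(abs(cdf_fit - emp)),
         n_tail = length(tail_len))
  }
  if (!is.null(lmin)) {
    out <- fit_at(as.integer(lmin))
    if (is.null(out)) stop("degenerate sample for the given lmin")
    return(out)
  }
  cands <- sort(unique(lengths))
  cands <- head(cands[cands < lmax], 15)
  fits <- Filter(Negate(is.null), lapply(cands, fit_at))
  # require a non-trivial tail so KS is meaningful
  fits <- Filter(function(f) f$n_tail >= max(10, 0.1 * length(lengths)), fits)
  if (length(fits) == 0) fits <- Filter(Negate(is.null),
                                        list(fit_at(min(cands))))
  if (length(fits) == 0) stop("could not fit a power law to the sample")
  fits[[which.min(vapply(fits, function(f) f$ks, 0))]]
}

#' Mixing probability of rings
#'
#' For each monomer of a ring, the fraction of beads within `probe_radius`
#' (any ring, excluding the central bead itself) that belong to *other*
#' rings, averaged over the ring's monomers: the probability of finding
#' foreign material in a probe sphere around the ring, a proxy for the
#' entropy of mixing. Rings whose monomers see no neighbours at all inside
#' the probe get 0 with `no_neighbours = TRUE`.
#'
#' @param state a [system_state].
#' @param ring ring index (from [extract_rings()]); `NULL` = all rings.
#' @param probe_radius probe sphere radius (sigma; default 2).
#' @return data frame with ring, length, mixing, no_neighbours.
#' @export
mixing_probability <- function(state, ring = NULL, probe_radius = 2) {
  stopifnot(inherits(state, "system_state"))
  rings <- extract_rings(state)
  pos <- state$positions
  ids <- if (is.null(ring)) seq_len(rings$count) else ring
  member <- integer(nrow(pos))
  for (i in seq_len(rings$count)) member[rings$rings[[i]]] <- i
  out <- lapply(ids, function(i) {
    beads <- rings$rings[[i]]
    fracs <- vapply(beads, function(b) {
      d2 <- rowSums(sweep(pos, 2, pos[b, ])^2)
      inside <- which(d2 <= probe_radius^2 & seq_along(d2) != b)
      if (length(inside) == 0) return(NA_real_)
      mean(member[inside] != i)
    }, 0)
    has <- !is.na(fracs)
    data.frame(ring = i, length = length(beads),
               mixing = if (any(has)) mean(fracs[has]) else 0,
               no_neighbours = !any(has))
  })
  do.call(rbind, out)
}

#' Radial density profile by ring length
#'
#' For each ring-length bin, the monomer count per spherical shell divided by
#' the shell volume and normalized by the bin's mean density over the whole
#' sphere, so a uniform distribution gives G(r) = 1 at every r. Summing
#' G(r) x shell volume x bin density over all shells and bins recovers the
#' total bead count exactly.
#'
#' @param frames a `trajectory_record`, a list of [system_state]s, or one
#'   state.
#' @param r_bin radial bin width (sigma; default 0.25).
#' @param length_breaks ring-length bin edges; `NULL` = logarithmic bins.
#' @param radius sphere radius (default: from the first frame's box).
#' @return data frame with length_bin (factor), r (shell midpoint), count,
#'   shell_volume, G.
#' @export
radial_density <- function(frames, r_bin = 0.25, length_breaks = NULL,
                           radius = NULL) {
  if (inherits(frames, "trajectory_record")) frames <- frames$frames
  if (inherits(frames, "system_state")) frames <- list(frames)
  stopifnot(length(frames) >= 1)
  if (is.null(radius)) {
    stopifnot(frames[[1]]$box$type == "sphere")
    radius <- frames[[1]]$box$radius
  }
  rr <- numeric(0)   # bead radial positions
  ll <- numeric(0)   # length of the ring each bead belongs to
  for (st in frames) {
    rings <- extract_rings(st)
    member_len <- integer(nrow(st$positions))
    for (i in seq_len(rings$count))
      member_len[rings$rings[[i]]] <- rings$lengths[i]
    rr <- c(rr, sqrt(rowSums(st$positions^2)))
    ll <- c(ll, member_len)
  }
  if (is.null(length_breaks)) {
    length_breaks <- unique(round(exp(seq(log(max(min(ll), 1) * 0.99),
                                          log(max(ll) * 1.01),
                                          length.out = 7))))
    if (length(length_breaks) < 2) length_breaks <- c(min(ll) - 1, max(ll))
  }
  lbin <- cut(ll, breaks = length_breaks, include.lowest = TRUE)
  edges <- (0:ceiling(radius / r_bin)) * r_bin
  rbin <- cut(pmin(rr, max(edges) - 1e-12), breaks = edges,
              include.lowest = TRUE)
  # cap the outermost shell at the wall so a uniform gas gives G = 1 there too
  shell_vol <- 4 / 3 * pi * diff(pmin(edges, radius)^3)
  vtot <- sum(shell_vol)
  counts <- table(lbin, rbin)         # length bins x radial shells
  nshell <- length(shell_vol)
  mids <- edges[-1] - r_bin / 2
  bin_tot <- rowSums(counts)
  out <- data.frame(
    length_bin = rep(rownames(counts), each = nshell),
    r = rep(mids, nrow(counts)),
    count = as.vector(t(counts)),
    shell_volume = rep(shell_vol, nrow(counts)))
  dens_bin <- rep(bin_tot, each = nshell) / vtot
  out$G <- ifelse(dens_bin > 0, (out$count / out$shell_volume) / dens_bin, 0)
  rownames(out) <- NULL
  out
}

#' Permeabilize the confining sphere and monitor escape
#'
#' Replaces the smooth confining wall by fixed repulsive sites on a Fibonacci
#' spherical lattice at the same radius, with the site spacing set by the
#' requested pore size (gap between site surfaces); sets the bending
#' constant to `post_K` (the reference protocol resets K = 1 for all
#' systems so only topology differs); optionally disallows further
#' reconnection; then integrates in a periodic box and records the number of
#' monomers still inside the sphere, n(t), at every sample. n(0) = N and
#' n(t) decays to ~0 for a liquid of small unlinked rings but plateaus when
#' a percolating linked network is trapped by the pores.
#'
#' @param state a steady-state [system_state] under spherical confinement.
#' @param pore_size pore diameter (sigma); below 1 sigma nothing fits
#'   through (warned).
#' @param post_K bending constant after permeabilization (default 1).
#' @param reconnect allow further reconnection (default FALSE).
#' @param run_length duration (tauB).
#' @param sample_interval sampling period (tauB).
#' @param box_length periodic box edge (default 4 R).
#' @param rc,min_ring_length reconnection settings when `reconnect = TRUE`.
#' @param ip an [integrator_params()].
#' @return an object of class `escape_experiment`: `times`, `n_t`,
#'   `pore_size`, `n_beads`, `mesh`, `final_state`.
#' @export
permeabilize_and_release <- function(state, pore_size, post_K = 1,
                                     reconnect = FALSE, run_length = 100,
                                     sample_interval = 1, box_length = NULL,
                                     rc = 1.3, min_ring_length = 3,
                                     ip = integrator_params()) {
  stopifnot(inherits(state, "system_state"),
            identical(state$box$type, "sphere"))
  if (pore_size < 1)
    warning("pore_size below the bead diameter: nothing can escape",
            call. = FALSE)
  R <- state$box$radius
  if (is.null(box_length)) box_length <- 4 * R
  stopifnot(box_length > 2 * R + 2)
  mesh <- fibonacci_sphere_mesh(R, pore_size)
  st <- state
  st$box <- periodic_box(box_length, mesh = mesh, mesh_radius = R)
  ff <- force_field(bending_k = post_K)
  sample_every <- max(1L, round(sample_interval / ip$timestep))
  n_steps <- round(run_length / ip$timestep)
  res <- run_engine(st, ff, ip, n_steps, sample_every = sample_every,
                    reconnect = reconnect, rc = rc,
                    min_ring_length = min_ring_length,
                    count_radius = R)
  n0 <- nrow(state$positions)
  structure(list(
    times = c(state$time, res$sample_times),
    n_t = c(n0, res$raw$n_inside),
    pore_size = pore_size, n_beads = n0, mesh = mesh,
    final_state = res$state), class = "escape_experiment")
}

#' @export
print.escape_experiment <- function(x, ...) {
  cat(sprintf(
    "escape_experiment: pore %.3g sigma, n(t): %d -> %d of %d beads inside\n",
    x$pore_size, x$n_t[1], tail(x$n_t, 1), x$n_beads))
  invisible(x)
}

# Fibonacci lattice of repulsive sites on a sphere of radius R; site spacing
# chosen so the surface gap between neighbouring unit-diameter sites is
# approximately pore_size.
fibonacci_sphere_mesh <- function(R, pore_size, site_diameter = 1) {
  d0 <- pore_size + site_diameter           # centre-to-centre spacing
  m <- max(4L, ceiling(4 * pi * R^2 / (sqrt(3) / 2 * d0^2)))
  i <- seq_len(m) - 0.5
  phi <- acos(1 - 2 * i / m)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(R * sin(phi) * cos(theta),
        R * sin(phi) * sin(theta),
        R * cos(phi))
}

#' Fit the escape curve
#'
#' Least-squares fit of a stretched exponential
#' \eqn{n(t) = n_0\exp(-(t/\tau)^\beta)} against a constant-plateau
#' alternative, selected by residual comparison. Strongly non-monotone
#' series are flagged unreliable.
#'
#' @param times sample times.
#' @param n_t monomers inside the sphere at those times.
#' @return list with `model` ("stretched" or "plateau"), `n0`, `tau`,
#'   `beta`, `plateau_fraction`, `sse`, `reliable`.
#' @export
fit_escape_curve <- function(times, n_t) {
  stopifnot(length(times) == length(n_t), length(n_t) >= 10)
  n0 <- n_t[1]
  reliable <- TRUE
  if (any(diff(n_t) > 0.1 * n0)) reliable <- FALSE
  dfit <- data.frame(t = times - times[1], n = n_t)
  plateau_level <- mean(tail(n_t, max(3, length(n_t) %/% 4)))
  sse_plateau <- sum((n_t - plateau_level)^2)
  fit <- tryCatch(
    minpack.lm::nlsLM(n ~ a * exp(-(t / tau)^beta), data = dfit,
                      start = list(a = n0, tau = max(median(dfit$t), 1e-6),
                                   beta = 1),
                      lower = c(0, 1e-9, 0.05), upper = c(Inf, Inf, 3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    sse_stretch <- sum(residuals(fit)^2)
    cf <- coef(fit)
  } else {
    sse_stretch <- Inf
    cf <- c(a = n0, tau = NA, beta = NA)
  }
  if (sse_plateau <= sse_stretch) {
    list(model = "plateau", n0 = n0, tau = NA_real_, beta = NA_real_,
         plateau_fraction = plateau_level / n0, sse = sse_plateau,
         reliable = reliable)
  } else {
    list(model = "stretched", n0 = unname(cf["a"]), tau = unname(cf["tau"]),
         beta = unname(cf["beta"]),
         plateau_fraction = tail(n_t, 1) / n0, sse = sse_stretch,
         reliable = reliable)
  }
}
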