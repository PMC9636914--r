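#' Integrator parameters
#'
#' Langevin thermostat settings for the velocity-Verlet integrator
#' (Gronbech-Jensen/Farago discretization, which reduces to plain symplectic
#' velocity Verlet when `friction = 0` -- the NVE limit used for testing).
#'
#' @param timestep integration step (tauB).
#' @param friction damping rate gamma (1/tauB); 1 is the Brownian convention.
#' @param temperature thermostat temperature (kBT units).
#' @param seed integer seed for the thermostat noise stream.
#' @return an object of class `integrator_params`.
#' @export
integrator_params <- function(timestep = 0.001, friction = 1,
                              temperature = 1, seed = 1) {
  stopifnot(timestep > 0, friction >= 0, temperature >= 0)
  structure(list(timestep = timestep, friction = friction,
                 temperature = temperature, seed = as.integer(seed)),
            class = "integrator_params")
}

# Low-level wrapper around the C++ engine. Times are converted to steps;
# returns the final state plus the per-sample series.
run_engine <- function(state, ff, ip, n_steps, sample_every = 0L,
                       wall_r_start = NULL, wall_r_end = NULL,
                       ramp_steps = 0L, reconnect = FALSE, rc = 1.3,
                       min_ring_length = 3L, seed = NULL,
                       store_frames = FALSE, count_radius = 0) {
  if (state$box$type == "sphere") {
    if (is.null(wall_r_start)) wall_r_start <- state$box$radius
    if (is.null(wall_r_end)) wall_r_end <- state$box$radius
  } else {
    wall_r_start <- wall_r_end <- 0
  }
  if (is.null(seed)) seed <- ip$seed
  res <- md_run_cpp(state$positions, state$velocities, state$bonds,
                    unclass(ff), state$box, ip$timestep, ip$friction,
                    ip$temperature, as.integer(n_steps),
                    as.integer(sample_every), wall_r_start, wall_r_end,
                    as.integer(ramp_steps), reconnect, rc,
                    as.integer(min_ring_length), as.integer(seed),
                    store_frames, count_radius)
  box <- state$box
  if (box$type == "sphere") box$radius <- res$wall_radius
  final <- system_state(res$positions, res$velocities, res$bonds,
                        time = state$time + n_steps * ip$timestep,
                        box = box, validate = FALSE)
  list(state = final, raw = res,
       sample_times = state$time + res$sample_step * ip$timestep)
}

#' Advance the system by one (or more) integration steps
#'
#' One velocity-Verlet/Langevin step advances positions and velocities by
#' `timestep`; the bond graph is untouched. Errors name the offending bead on
#' FENE overextension or non-finite coordinates.
#'
#' @param state a [system_state].
#' @param ff a [force_field()].
#' @param ip an [integrator_params()].
#' @param n_steps number of steps to take.
#' @return the advanced [system_state].
#' @export
md_step <- function(state, ff, ip, n_steps = 1) {
  run_engine(state, ff, ip, n_steps)$state
}

#' Compression schedule
#'
#' Linear shrinking ramp of the confining sphere followed by equilibration at
#' the final radius. The default ramp speed is 0.05 sigma/tauB, slow compared
#' with the free-bead diffusive speed so the wall never piles beads up.
#'
#' @param initial_radius,final_radius wall radii (sigma).
#' @param compression_time ramp duration (tauB); default
#'   `(initial_radius - final_radius) / 0.05`.
#' @param post_equilibration_time time at the final radius (tauB).
#' @return an object of class `compression_schedule`.
#' @export
compression_schedule <- function(initial_radius, final_radius,
                                 compression_time = NULL,
                                 post_equilibration_time = 100) {
  stopifnot(initial_radius >= final_radius, final_radius > 0)
  if (is.null(compression_time))
    compression_time <- (initial_radius - final_radius) / 0.05
  structure(list(initial_radius = initial_radius,
                 final_radius = final_radius,
                 compression_time = compression_time,
                 post_equilibration_time = post_equilibration_time),
            class = "compression_schedule")
}

#' Compress the confining sphere and equilibrate
#'
#' Shrinks the wall radius linearly from `initial_radius` to `final_radius`
#' over `compression_time`, then holds it fixed for
#' `post_equilibration_time`. A warning is issued when the configured ramp is
#' faster than 0.2 sigma/tauB, where the wall starts doing appreciable work
#' on the beads per step.
#'
#' @param state a [system_state] whose beads all lie inside `initial_radius`.
#' @param schedule a [compression_schedule()].
#' @param ff a [force_field()].
#' @param ip an [integrator_params()].
#' @return the compressed, equilibrated [system_state] (wall at
#'   `final_radius`).
#' @export
compress <- function(state, schedule, ff, ip) {
  stopifnot(inherits(schedule, "compression_schedule"))
  rmax <- max(sqrt(rowSums(state$positions^2)))
  if (rmax >= schedule$initial_radius)
    stop("beads outside the initial sphere radius")
  if (schedule$compression_time > 0) {
    rate <- (schedule$initial_radius - schedule$final_radius) /
      schedule$compression_time
    if (rate > 0.2)
      warning(sprintf(
        "compression rate %.3g sigma/tauB exceeds 0.2: ramp may be too fast",
        rate), call. = FALSE)
  }
  ramp_steps <- round(schedule$compression_time / ip$timestep)
  total_steps <- ramp_steps +
    round(schedule$post_equilibration_time / ip$timestep)
  if (total_steps == 0) {
    state$box$radius <- schedule$final_radius
    return(state)
  }
  run_engine(state, ff, ip, total_steps,
             wall_r_start = schedule$initial_radius,
             wall_r_end = schedule$final_radius,
             ramp_steps = ramp_steps)$state
}

#' Production run with reconnection moves
#'
#' Alternates one Langevin integration step with one reconnection sweep (bond
#' swaps are attempted at every integration step between bead pairs closer
#' than `config$reconnection_cutoff` and accepted by the Metropolis rule).
#' Every `config$sample_interval` the full configuration is recorded along
#' with the ring census Nr(t), the ring length list Lr(n, t) and the swap
#' statistics; the accepted-swap rate kappa_r is reported over a trailing
#' window.
#'
#' @param state an equilibrated [system_state].
#' @param config a [simulation_config()]; supplies run length, sampling,
#'   cutoff, minimum ring length and seed.
#' @param ff a [force_field()] (defaults to `config$stiffness`).
#' @param ip an [integrator_params()] (defaults to `config`'s timestep/seed).
#' @param reconnect set `FALSE` to freeze the topology (no swaps attempted).
#' @param analyze also build the link network of every sampled frame and
#'   record N_Lk(t), |Lk|(t) and cluster statistics.
#' @param kappa_window trailing window (tauB) for the kappa_r estimate.
#' @return a `trajectory_record`: sample times, Nr(t), ring lengths, swap
#'   counters, kappa_r(t), energies, the sampled frames, and (with
#'   `analyze = TRUE`) the per-frame topology table.
#' @export
run_with_reconnection <- function(state, config, ff = NULL, ip = NULL,
                                  reconnect = TRUE, analyze = FALSE,
                                  kappa_window = 100) {
  if (is.null(ff)) ff <- force_field(bending_k = config$stiffness)
  if (is.null(ip)) ip <- integrator_params(timestep = config$timestep,
                                           seed = config$seed)
  sample_every <- round(config$sample_interval / ip$timestep)
  n_steps <- round(config$run_length / ip$timestep)
  rs0 <- extract_rings(state)
  res <- run_engine(state, ff, ip, n_steps, sample_every = sample_every,
                    reconnect = reconnect,
                    rc = config$reconnection_cutoff,
                    min_ring_length = config$min_ring_length,
                    seed = config$seed, store_frames = TRUE)
  raw <- res$raw
  # prepend the t = 0 sample so sample times are {0, dt_s, 2 dt_s, ...}
  times <- c(state$time, res$sample_times)
  nr <- c(rs0$count, raw$nr)
  ring_lengths <- c(list(sort(rs0$lengths, decreasing = TRUE)),
                    raw$ring_lengths)
  cum_acc <- c(0, raw$cum_accepts)
  cum_att <- c(0, raw$cum_attempts)
  kappa <- kappa_series(times, cum_acc, kappa_window)
  frames <- c(list(list(positions = state$positions, bonds = state$bonds)),
              raw$frames)
  frames <- lapply(seq_along(frames), function(i) {
    system_state(frames[[i]]$positions, bonds = frames[[i]]$bonds,
                 time = times[i], box = res$state$box, validate = FALSE)
  })
  rec <- structure(list(
    times = times, nr = nr, ring_lengths = ring_lengths,
    mean_lr = vapply(ring_lengths, function(l) mean(l), 0),
    attempts = cum_att, accepts = cum_acc, kappa_r = kappa,
    kinetic = c(NA, raw$kinetic), potential = c(NA, raw$potential),
    frames = frames, final_state = res$state, config = config),
    class = "trajectory_record")
  if (analyze) rec <- analyze_trajectory(rec)
  rec
}

kappa_series <- function(times, cum_accepts, window) {
  vapply(seq_along(times), function(i) {
    j <- which(times >= times[i] - window)[1]
    if (j == i) j <- max(1, i - 1)
    dt <- times[i] - times[j]
    if (dt <= 0) return(NA_real_)
    (cum_accepts[i] - cum_accepts[j]) / dt
  }, 0)
}

#' Topological analysis of a trajectory
#'
#' Builds the link network of every sampled frame and attaches the per-frame
#' series N_Lk(t) (number of linked pairs), |Lk|(t) (total unsigned linking
#' number), the largest-cluster fraction and the single-cluster indicator.
#'
#' @param record a `trajectory_record`.
#' @return the record with a `topology` data frame and a `networks` list.
#' @export
analyze_trajectory <- function(record) {
  stopifnot(inherits(record, "trajectory_record"))
  nets <- lapply(record$frames, build_link_network)
  record$networks <- nets
  record$topology <- data.frame(
    time = record$times,
    nr = record$nr,
    n_lk = vapply(nets, function(n) n$n_lk, 0),
    abs_lk = vapply(nets, function(n) n$abs_lk, 0),
    largest_cluster_fraction =
      vapply(nets, function(n) n$largest_cluster_fraction, 0),
    single_cluster = vapply(nets, function(n) n$single_cluster, NA))
  record
}

#' @export
print.trajectory_record <- function(x, ...) {
  cat(sprintf(
    "trajectory_record: %d samples over %.4g tauB; Nr %d -> %d; %d accepted swaps\n",
    length(x$times), diff(range(x$times)), x$nr[1], tail(x$nr, 1),
    as.integer(tail(x$accepts, 1))))
  invisible(x)
}
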