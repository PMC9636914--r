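#' Simulation configuration
#'
#' Bundles the physical and numerical parameters of a reconnecting-ring run.
#' Defaults correspond to the reference system: `n_beads = 1000` beads of
#' diameter \eqn{\sigma} confined to a sphere of radius `sphere_radius = 7`
#' \eqn{\sigma} (monomer density \eqn{\rho \simeq 0.7\sigma^{-3}}, volume
#' fraction \eqn{\phi \simeq 0.37}), reconnection cutoff
#' \eqn{r_c = 1.3\sigma}, timestep \eqn{\Delta t = 10^{-3}\tau_B} and one
#' configuration sample every \eqn{100\tau_B}.
#'
#' @param n_beads integer, total number of beads N (conserved by reconnection).
#' @param stiffness bending constant K in units of kBT; the persistence length
#'   is `persistence_length(K)`.
#' @param sphere_radius confinement radius R in sigma.
#' @param reconnection_cutoff maximum bead-bead distance rc (sigma) at which a
#'   bond swap may be proposed.
#' @param timestep integration step in tauB; must lie in (0, 0.01].
#' @param sample_interval time between recorded snapshots (tauB).
#' @param seed integer RNG seed for the run.
#' @param run_length production run duration (tauB).
#' @param min_ring_length smallest ring the reconnection move may create; a
#'   cycle needs at least 3 beads to carry bending angles.
#' @return an object of class `simulation_config` (a validated list).
#' @seealso [read_config()], [write_config()], [derived_densities()]
#' @export
simulation_config <- function(n_beads = 1000, stiffness = 0, sphere_radius = 7,
                              reconnection_cutoff = 1.3, timestep = 0.001,
                              sample_interval = 100, seed = 1,
                              run_length = 1000, min_ring_length = 3) {
  cfg <- list(
    n_beads = as.integer(n_beads), stiffness = as.numeric(stiffness),
    sphere_radius = as.numeric(sphere_radius),
    reconnection_cutoff = as.numeric(reconnection_cutoff),
    timestep = as.numeric(timestep),
    sample_interval = as.numeric(sample_interval),
    seed = as.integer(seed), run_length = as.numeric(run_length),
    min_ring_length = as.integer(min_ring_length))
  class(cfg) <- "simulation_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_beads >= cfg$min_ring_length, cfg$sphere_radius > 0,
            cfg$timestep > 0, cfg$timestep <= 0.01,
            cfg$reconnection_cutoff > 0, cfg$min_ring_length >= 3,
            cfg$stiffness >= 0, cfg$run_length >= 0,
            cfg$sample_interval > 0)
  if (cfg$reconnection_cutoff >= 1.5)
    warning("reconnection_cutoff >= FENE maximum extension (1.5 sigma): ",
            "proposals near the cutoff can never be accepted", call. = FALSE)
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config:\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k, format(x[[k]])))
  dd <- derived_densities(x)
  cat(sprintf("  (rho = %.3f sigma^-3, phi = %.3f)\n",
              dd$monomer_density, dd$volume_fraction))
  invisible(x)
}

#' Read / write a configuration file
#'
#' Flat `key = value` text, one field per line, keys named exactly as the
#' [simulation_config()] fields. Unknown keys raise an error.
#'
#' @param path file path.
#' @return `read_config` returns a `simulation_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  allowed <- names(formals(simulation_config))
  if (any(!keys %in% allowed))
    stop("unknown config key: ", paste(setdiff(keys, allowed), collapse = ", "))
  args <- as.list(as.numeric(vals))
  names(args) <- keys
  do.call(simulation_config, args)
}

#' @rdname read_config
#' @param config a `simulation_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  writeLines(sprintf("%s = %.17g", names(config),
                     vapply(config, as.numeric, 0)), path)
  invisible(path)
}

#' Monomer density and volume fraction of a confined system
#'
#' \eqn{\rho = 3N/(4\pi R^3)} and \eqn{\phi = (\pi/6)\rho\sigma^3} (volume
#' fraction of spheres of diameter \eqn{\sigma}). For the reference system
#' N = 1000, R = 7 this gives \eqn{\rho \simeq 0.70\sigma^{-3}} and
#' \eqn{\phi \simeq 0.37}.
#'
#' @param config a [simulation_config()], or a list with `n_beads` and
#'   `sphere_radius`.
#' @return list with `monomer_density` and `volume_fraction`.
#' @export
derived_densities <- function(config) {
  n <- config$n_beads
  r <- config$sphere_radius
  stopifnot(r > 0, n >= 0)
  rho <- 3 * n / (4 * pi * r^3)
  list(monomer_density = rho, volume_fraction = pi / 6 * rho)
}

#' Persistence length of the Kratky-Porod chain
#'
#' Maps the bending constant K to a persistence length. The large-K mapping
#' for the discrete worm-like chain with bending energy \eqn{K(1-\cos\theta)}
#' and unit bond length is \eqn{l_p = K\sigma}, used as the default throughout
#' (the theory module accepts any alternative mapping).
#'
#' @param stiffness bending constant K (kBT).
#' @param sigma bead diameter (reduced units; default 1).
#' @return persistence length in sigma.
#' @export
persistence_length <- function(stiffness, sigma = 1) {
  stopifnot(all(stiffness >= 0))
  stiffness * sigma
}
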