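#' Langevin integrator configuration
#'
#' Parameters of the stochastic dynamics: each bead obeys
#' m r'' = -grad U - m zeta r' + F_R(t), with the random force variance tied
#' to the friction by the fluctuation-dissipation theorem (discretized as
#' variance 2 m zeta kBT dt per Cartesian component per step). The integrator
#' is the Gronbech-Jensen-Farago splitting, which reduces to velocity Verlet
#' when `zeta = 0` or `thermostat_off = TRUE` (NVE validation runs).
#'
#' @param dt time step (tau).
#' @param zeta friction coefficient (1/tau).
#' @param temperature target temperature (kBT).
#' @param n_steps production steps.
#' @param save_stride store a frame every `save_stride` steps.
#' @param seed integer seed for the noise stream (recorded in the trajectory).
#' @param equilibration steps discarded before production (default 2e5 at
#'   production scale; pass smaller values for desk-scale runs).
#' @param thermostat_off disable friction and noise (NVE).
#' @param mass bead mass (m units).
#' @param skin Verlet-list skin (sigma); the list is rebuilt when any bead has
#'   moved more than `skin/2` since the last build.
#' @return an object of class `integrator_config`.
#' @export
integrator_config <- function(dt = 0.005, zeta = 1.0, temperature = 1.0,
                              n_steps = 1e5, save_stride = 200, seed = 1,
                              equilibration = 2e5, thermostat_off = FALSE,
                              mass = 1, skin = 0.4) {
  stopifnot(dt > 0, zeta >= 0, save_stride >= 1, n_steps >= 0,
            equilibration >= 0, mass > 0, temperature > 0)
  structure(list(dt = dt, zeta = zeta, temperature = temperature,
                 n_steps = as.double(n_steps),
                 save_stride = as.integer(save_stride),
                 seed = as.integer(seed),
                 equilibration = as.double(equilibration),
                 thermostat_off = isTRUE(thermostat_off), mass = mass,
                 skin = skin),
            class = "integrator_config")
}

maxwell_velocities <- function(n, temperature, mass, seed) {
  with_seed(seed, matrix(rnorm(3 * n, sd = sqrt(temperature / mass)), n, 3))
}

#' Run Langevin dynamics
#'
#' Integrates a `particle_system` under the configured Langevin dynamics,
#' discards the equilibration segment, and returns a trajectory of unwrapped
#' coordinates saved every `save_stride` steps (the first production frame is
#' the post-equilibration state). Velocities are drawn from the
#' Maxwell-Boltzmann distribution at the target temperature unless the system
#' already carries a `velocities` field.
#'
#' @param sys a `particle_system`.
#' @param params a [force_field()].
#' @param icfg an [integrator_config()].
#' @param save_species which beads to store per frame: `"all"` or `"rod"`
#'   (rod beads only, which is all the diffusion analysis needs and keeps
#'   trajectories small).
#' @return an object of class `trajectory`: `times` (tau), `frames`
#'   (n_frames x n_saved_beads x 3 array, unwrapped sigma), `box_lengths`,
#'   `species`/`molecule_id` of the saved beads, per-frame kinetic/potential
#'   energy series, the run-mean kinetic energy per bead
#'   (`ke_mean_per_bead`, measured with the half-step velocity, the
#'   statistically unbiased thermometer for this integrator), and the final
#'   state.
#' @export
run_langevin <- function(sys, params, icfg, save_species = c("all", "rod")) {
  stopifnot(inherits(sys, "particle_system"), inherits(params, "force_field"),
            inherits(icfg, "integrator_config"))
  save_species <- match.arg(save_species)
  n <- nrow(sys$positions)
  vel <- if (!is.null(sys$velocities)) sys$velocities
         else maxwell_velocities(n, icfg$temperature, icfg$mass, icfg$seed)
  save_idx <- if (save_species == "rod") which(sys$molecule_id > 0L) else seq_len(n)
  if (length(save_idx) == 0) stop("no beads selected for saving")

  res <- cpp_run_langevin(
    unwrapped_positions(sys), vel, sys$box_lengths,
    species_index(sys$species), params$sigma_table, params$epsilon,
    params$rcut_factor, bonds_matrix(sys), angles_matrix(sys),
    angle_ka_vector(sys, params), as.integer(sys$tether_idx),
    tether_anchor_matrix(sys), params$kb, params$r0, params$theta0,
    params$k_tether, icfg$dt, icfg$zeta, icfg$temperature, icfg$mass,
    as.integer(icfg$n_steps), icfg$save_stride, as.integer(icfg$equilibration),
    icfg$seed, icfg$thermostat_off, icfg$skin, as.integer(save_idx))

  final <- sys
  w <- wrap_positions(res$final_pos, sys$box_lengths)
  final$positions <- w$wrapped
  final$image_counts <- w$image
  final$velocities <- res$final_vel

  structure(list(
    times = res$times, frames = res$frames, box_lengths = sys$box_lengths,
    species = sys$species[save_idx], molecule_id = sys$molecule_id[save_idx],
    dt_frame = icfg$dt * icfg$save_stride,
    ke_series = res$ke_series, pe_series = res$pe_series,
    ke_mean_per_bead = res$ke_mean_per_bead, n_beads_total = n,
    n_rebuilds = res$n_rebuilds, seed = icfg$seed, config = icfg,
    final_system = final), class = "trajectory")
}

#' Advance a system by a single Langevin step
#'
#' One integrator step at the configured `dt`; mainly useful for testing and
#' for custom stepping loops. Equivalent to [run_langevin()] with
#' `n_steps = 1` and no equilibration, but returns the updated system.
#'
#' @inheritParams run_langevin
#' @return the updated `particle_system` (with a `velocities` field).
#' @export
step_langevin <- function(sys, params, icfg) {
  icfg$n_steps <- 1
  icfg$equilibration <- 0
  icfg$save_stride <- 1L
  run_langevin(sys, params, icfg)$final_system
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>\n")
  cat(sprintf("  frames: %d x %d beads, dt_frame = %g tau (span %g tau)\n",
              length(x$times), dim(x$frames)[2], x$dt_frame, max(x$times)))
  cat(sprintf("  box: %s sigma, seed %d, mean KE/bead = %.4f kBT\n",
              paste(x$box_lengths, collapse = " x "), x$seed,
              x$ke_mean_per_bead))
  invisible(x)
}
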