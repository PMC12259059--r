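# Langevin dynamics driver: BAOAB-split velocity-Verlet with per-particle
# friction gamma_i = m_i / t_damp, periodic boundaries and cell-list
# neighbor search (compiled kernels in src/).

#' Thermostat and integration parameters
#'
#' @param temperature target temperature, K.
#' @param t_damp_ps Langevin damping time, ps; the friction coefficient is
#'   `gamma_i = m_i / t_damp` so every particle relaxes its velocity on the
#'   same timescale.
#' @param dt_fs integration time step, fs.
#' @param seed integer seed for the thermal-noise stream (counter-based:
#'   keyed by (seed, step, particle), so restarts are exact).
#' @return object of class `thermostat_params`.
#' @export
thermostat_params <- function(temperature = 300, t_damp_ps = 1000,
                              dt_fs = 10, seed = 1L) {
  stopifnot(temperature > 0, t_damp_ps > 0, dt_fs > 0)
  structure(list(temperature = temperature, t_damp_ps = t_damp_ps,
                 dt_fs = dt_fs, seed = as.integer(seed)),
            class = "thermostat_params")
}

#' Draw Maxwell-Boltzmann velocities
#' @param topology a `cg_topology`.
#' @param model an [interaction_model()] (for masses).
#' @param temperature K.
#' @return N x 3 velocity matrix, A per internal time unit.
#' @export
maxwell_velocities <- function(topology, model, temperature = 300) {
  m <- model$species$mass[topology$type]
  matrix(rnorm(length(m) * 3), ncol = 3) *
    sqrt(.kB * temperature / m)
}

#' Run Langevin (or NVE) dynamics
#'
#' Integrates the equations of motion with the BAOAB splitting of
#' velocity-Verlet: friction and fluctuation-dissipation-consistent noise
#' are applied in the middle of the step.  With `nve = TRUE` the
#' friction/noise substep is skipped, giving plain velocity-Verlet
#' (microcanonical), useful for energy-conservation checks.  Positions are
#' wrapped into the box with image flags tracked, so unwrapped coordinates
#' are always recoverable.  Fixed seed gives a bit-identical trajectory,
#' and a continuation ([continue_simulation()]) reproduces exactly what a
#' single longer run would have produced.
#'
#' @param topology a `cg_topology`.
#' @param config initial `cg_configuration`.
#' @param model an [interaction_model()].
#' @param params a [thermostat_params()].
#' @param n_steps number of steps (0 returns the initial frame only).
#' @param cadence frames are stored every `cadence` steps.
#' @param velocities optional N x 3 initial velocities (internal units);
#'   default Maxwell-Boltzmann at the thermostat temperature.
#' @param nve skip friction and noise (microcanonical run).
#' @param force_cap if positive, per-particle forces are clipped to this
#'   magnitude (kcal/mol/A) -- used for pre-relaxation ramps.
#' @param skin neighbor-list skin, A; lists rebuild when any particle has
#'   moved half a skin.
#' @param quiet suppress the run banner.
#' @return object of class `cg_trajectory`.
#' @export
run_simulation <- function(topology, config, model, params,
                           n_steps, cadence = max(1L, n_steps %/% 100L),
                           velocities = NULL, nve = FALSE, force_cap = 0,
                           skin = 15, quiet = FALSE) {
  n <- nrow(config$pos)
  check_topology(topology, n)
  stopifnot(n_steps >= 0, cadence >= 1)
  if (is.null(velocities)) {
    set.seed(params$seed)
    velocities <- maxwell_velocities(topology, model, params$temperature)
  }
  mass <- model$species$mass[topology$type]
  excl <- if (model$exclude_bonded) bonded_exclusions(topology) else
    matrix(integer(0), 0, 2)
  if (!quiet)
    message(sprintf("condensr: %d particles, %d steps, dt = %g fs, T = %g K%s",
                    n, n_steps, params$dt_fs, params$temperature,
                    if (nve) " (NVE)" else ""))
  if (n_steps == 0) {
    traj <- new_trajectory(topology, model, params, config$box)
    traj$frames <- list(list(step = config$step, time_fs = config$time_fs,
                             pos = config$pos, img = config$img))
    traj$velocities <- velocities
    traj$final_step <- config$step
    return(traj)
  }
  out <- cpp_run_langevin(config$pos, velocities, config$img,
                          topology$type - 1L, .model_cpp(model),
                          zero_index(topology$bonds),
                          zero_index(topology$angles), zero_index(excl),
                          mass, config$box,
                          fs_to_tau(params$dt_fs), params$temperature,
                          fs_to_tau(params$t_damp_ps * 1000),
                          as.integer(n_steps), as.integer(cadence),
                          params$seed, as.integer(config$step),
                          isTRUE(nve), force_cap, skin)
  traj <- new_trajectory(topology, model, params, config$box)
  traj$frames <- lapply(seq_along(out$frames_pos), function(i)
    list(step = out$frame_step[i],
         time_fs = out$frame_step[i] * params$dt_fs,
         pos = out$frames_pos[[i]], img = out$frames_img[[i]]))
  el <- as.data.frame(out$energy_log)
  el$total <- el$ekin + el$bond + el$angle + el$pair
  el$T_kin <- 2 * el$ekin / (3 * n * .kB)
  el$time_fs <- el$step * params$dt_fs
  traj$energy_log <- el
  traj$velocities <- out$velocities
  traj$final_step <- out$final_step
  traj
}

new_trajectory <- function(topology, model, params, box) {
  structure(list(topology = topology, model = model, params = params,
                 box = box, frames = list(), energy_log = NULL,
                 velocities = NULL, final_step = 0L),
            class = "cg_trajectory")
}

#' Continue a simulation from its last frame
#'
#' Uses the stored velocities, step counter and seed; because the noise is
#' keyed by absolute step index, the continuation is bit-identical to a
#' single longer run.
#'
#' @param traj a `cg_trajectory` from [run_simulation()].
#' @param n_steps additional steps.
#' @param cadence output cadence.
#' @param ... passed to [run_simulation()].
#' @return a `cg_trajectory` for the continuation segment.
#' @export
continue_simulation <- function(traj, n_steps,
                                cadence = max(1L, n_steps %/% 100L), ...) {
  last <- get_frame(traj, n_frames(traj))
  run_simulation(traj$topology, last, traj$model, traj$params, n_steps,
                 cadence, velocities = traj$velocities, quiet = TRUE, ...)
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("cg_trajectory:", length(x$frames), "frames,",
      length(x$topology$type), "particles, box", x$box, "A\n")
  if (!is.null(x$energy_log)) {
    n <- nrow(x$energy_log)
    cat(sprintf("  last frame: step %d, T_kin = %.1f K, E = %.2f kcal/mol\n",
                x$energy_log$step[n], x$energy_log$T_kin[n],
                x$energy_log$total[n]))
  }
  invisible(x)
}

#' Number of stored frames
#' @param traj a `cg_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Extract one frame as a configuration
#' @param traj a `cg_trajectory`.
#' @param i frame index (1-based).
#' @return a `cg_configuration`.
#' @export
get_frame <- function(traj, i) {
  f <- traj$frames[[i]]
  configuration(f$pos, traj$box, img = f$img, step = f$step,
                time_fs = f$time_fs)
}

#' Build a neighbor structure for one configuration
#'
#' Every (unordered) pair within `cutoff` under the minimum-image
#' convention, inclusive of pairs at exactly the cutoff.
#'
#' @param config a `cg_configuration`.
#' @param cutoff pair cutoff, A.
#' @param skin extra margin added to the stored list, A.
#' @return list with `pairs` (two-column 1-based matrix), `cutoff`, `skin`.
#' @export
build_neighbor_list <- function(config, cutoff, skin = 0) {
  if (cutoff + skin >= config$box / 2)
    stop("geometry error: cutoff + skin must be below half the box edge")
  list(pairs = cpp_neighbor_pairs(config$pos, config$box, cutoff + skin),
       cutoff = cutoff, skin = skin)
}
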