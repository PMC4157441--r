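#' Slow-cooling annealing schedule
#'
#' The default schedule is the classic slow-cooling protocol: start at 3000 K,
#' cool to 0 K in 50 K decrements, six dynamics steps per temperature level
#' with a 4 fs integration step — 60 levels and 1.44 ps of simulated time.
#' With the Cartesian integrator used here a 1 fs step is recommended (stiff
#' bond terms); the 4 fs default is retained as the descriptive constant of
#' the protocol itself.
#'
#' @param t_start starting temperature (K).
#' @param t_end final temperature (K); levels run down to but excluding it.
#' @param dt_temp temperature decrement per level (K).
#' @param steps_per_level dynamics steps at each level.
#' @param timestep integration time step (fs).
#' @return an object of class `den_schedule`.
#' @export
annealing_schedule <- function(t_start = 3000, t_end = 0, dt_temp = 50,
                               steps_per_level = 6, timestep = 4) {
  if (!(t_start > t_end && t_end >= 0)) stop("need t_start > t_end >= 0")
  if (dt_temp <= 0) stop("need dt_temp > 0")
  structure(list(t_start = t_start, t_end = t_end, dt_temp = dt_temp,
                 steps_per_level = as.integer(steps_per_level),
                 timestep = timestep),
            class = "den_schedule")
}

#' @rdname annealing_schedule
#' @param schedule a `den_schedule`.
#' @export
schedule_levels <- function(schedule) {
  seq(schedule$t_start, schedule$t_end + schedule$dt_temp,
      by = -schedule$dt_temp)
}

#' @rdname annealing_schedule
#' @export
total_simulated_time_ps <- function(schedule) {
  length(schedule_levels(schedule)) * schedule$steps_per_level *
    schedule$timestep / 1000
}

#' @export
print.den_schedule <- function(x, ...) {
  cat(sprintf(
    "den_schedule: %g -> %g K in %g K decrements (%d levels), %d x %g fs/level, %.3g ps total\n",
    x$t_start, x$t_end, x$dt_temp, length(schedule_levels(x)),
    x$steps_per_level, x$timestep, total_simulated_time_ps(x)))
  invisible(x)
}

#' Dynamics state
#'
#' Positions (Angstrom), velocities (Angstrom/fs) and element masses (amu) for
#' Cartesian molecular dynamics.
#'
#' @param structure a [den_structure()].
#' @return an object of class `den_dynamics_state`.
#' @export
dynamics_state <- function(structure) {
  structure(list(
    xyz = coords(structure),
    vel = matrix(0, n_atoms(structure), 3),
    masses = element_lookup(structure$atoms$element, "mass")
  ), class = "den_dynamics_state")
}

#' Instantaneous kinetic temperature
#'
#' `T = 2 KE / (3 N kB)` with the kinetic energy in kcal/mol over all `3N`
#' Cartesian degrees of freedom.
#'
#' @param state a [dynamics_state()].
#' @return temperature in K.
#' @export
kinetic_temperature <- function(state) {
  ke <- 0.5 * sum(state$masses * rowSums(state$vel^2)) / .acc_conv
  2 * ke / (3 * nrow(state$xyz) * .kB)
}

#' Maxwell-Boltzmann velocity assignment
#'
#' Draws each velocity component from the Maxwell-Boltzmann distribution at
#' the given temperature (deterministically by seed) and removes the
#' center-of-mass momentum.
#'
#' @param state a [dynamics_state()].
#' @param temperature target temperature (K).
#' @param seed integer seed.
#' @return the state with new velocities.
#' @export
assign_velocities <- function(state, temperature, seed = 1) {
  stopifnot(temperature >= 0)
  n <- nrow(state$xyz)
  if (temperature == 0) {
    state$vel <- matrix(0, n, 3)
    return(state)
  }
  sdv <- sqrt(.kB * temperature * .acc_conv / state$masses)
  v <- with_seed(seed, matrix(rnorm(3 * n), n, 3)) * sdv
  p <- colSums(state$masses * v)
  v <- sweep(v, 2, p / sum(state$masses))
  state$vel <- v
  state
}

# Exact velocity rescale to a target kinetic temperature.
rescale_velocities <- function(state, temperature) {
  tc <- kinetic_temperature(state)
  if (tc > 0) state$vel <- state$vel * sqrt(temperature / tc)
  state
}

#' Velocity-Verlet integration
#'
#' Integrates `n_steps` of Newtonian dynamics under `force_fn`, a function of
#' an n x 3 coordinate matrix returning `list(energy=, forces=)` in
#' kcal/mol and kcal/mol/Angstrom. No thermostat is applied, so with a
#' conservative `force_fn` this samples the NVE ensemble.
#'
#' @param state a [dynamics_state()].
#' @param n_steps number of steps.
#' @param dt_fs time step (fs).
#' @param force_fn force field callback, see above.
#' @return list with the advanced `state` and a numeric vector `e_total`
#'   (potential + kinetic, one entry per step).
#' @export
run_md <- function(state, n_steps, dt_fs, force_fn) {
  xyz <- state$xyz
  vel <- state$vel
  minv <- .acc_conv / state$masses
  ev <- force_fn(xyz)
  acc <- ev$forces * minv
  e_total <- numeric(n_steps)
  for (step in seq_len(n_steps)) {
    xyz <- xyz + vel * dt_fs + 0.5 * acc * dt_fs^2
    ev <- force_fn(xyz)
    if (!is.finite(ev$energy)) stop("instability: non-finite energy at step ", step)
    acc_new <- ev$forces * minv
    vel <- vel + 0.5 * (acc + acc_new) * dt_fs
    acc <- acc_new
    ke <- 0.5 * sum(state$masses * rowSums(vel^2)) / .acc_conv
    e_total[step] <- ev$energy + ke
  }
  state$xyz <- xyz
  state$vel <- vel
  list(state = state, e_total = e_total)
}

#' Slow-cooling simulated annealing with deforming DEN restraints
#'
#' At each temperature level: velocities are rescaled to the level
#' temperature, `steps_per_level` velocity-Verlet steps are integrated under
#' the composite target, and then the DEN equilibrium distances are deformed
#' exactly once via [update_equilibrium()] (or before the level's dynamics
#' when `update_before_dynamics` is `TRUE`). The number of deformation updates
#' therefore equals the number of temperature levels.
#'
#' @param state a [dynamics_state()] (assign initial velocities first).
#' @param schedule an [annealing_schedule()].
#' @param network a `den_network`.
#' @param energies composite evaluator `function(xyz, network)` returning
#'   `list(energy, forces, e_mm, e_xray, e_den)`; it must already include the
#'   DEN term at the desired weight.
#' @param gamma deformation parameter in `[0, 1]`.
#' @param kappa update rate in `(0, 1]`.
#' @param update_before_dynamics logical; order of update vs. dynamics within
#'   a level.
#' @return list with `state`, `network`, and a per-level `trace` data.frame
#'   (level, temperature, e_total, e_mm, e_xray, e_den_pre, e_den_post).
#' @export
run_slow_cooling <- function(state, schedule, network, energies,
                             gamma, kappa = 0.1,
                             update_before_dynamics = FALSE) {
  temps <- schedule_levels(schedule)
  nlev <- length(temps)
  trace <- data.frame(level = seq_len(nlev), temperature = temps,
                      e_total = NA_real_, e_mm = NA_real_, e_xray = NA_real_,
                      e_den_pre = NA_real_, e_den_post = NA_real_)
  den_energy <- attr(energies, "den_energy") %||%
    function(xyz, network) energies(xyz, network)$e_den
  for (lev in seq_len(nlev)) {
    do_update <- function() {
      pre <- den_energy(state$xyz, network)
      network <<- update_equilibrium(network, state$xyz, gamma, kappa)
      c(pre = pre, post = den_energy(state$xyz, network))
    }
    if (update_before_dynamics) ed <- do_update()
    state <- rescale_velocities(state, temps[lev])
    res <- tryCatch(
      run_md(state, schedule$steps_per_level, schedule$timestep,
             function(xyz) energies(xyz, network)),
      error = function(e) stop("instability at level ", lev, " (T = ",
                               temps[lev], " K): ", conditionMessage(e)))
    state <- res$state
    if (!update_before_dynamics) ed <- do_update()
    ev <- energies(state$xyz, network)
    trace[lev, c("e_total", "e_mm", "e_xray", "e_den_pre", "e_den_post")] <-
      c(utils::tail(res$e_total, 1), ev$e_mm, ev$e_xray, ed["pre"], ed["post"])
  }
  list(state = state, network = network, trace = trace)
}
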