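#' Refinement configuration
#'
#' Bundles every tunable of a DEN refinement. Defaults follow the recommended
#' protocol: `kappa = 0.1`; nondeformable (`gamma = 0`) restraints in the
#' first macrocycle; the DEN term switched off (`w_den = 0`) for the last two
#' macrocycles as a convergence probe; `gamma = 0`, `w_den = 100` as the
#' single-shot recommendation when the model is already close. The macrocycle
#' total of 8 is 1 (gamma = 0) + 5 (chosen gamma) + 2 (released).
#'
#' @param gamma deformation parameter in `[0, 1]`.
#' @param w_den DEN weight (>= 0).
#' @param w_xray X-ray weight, or `"auto"` for gradient-norm matching
#'   recomputed at each macrocycle start.
#' @param kappa DEN update rate.
#' @param n_macrocycles number of macrocycles (>= 1).
#' @param first_cycle_gamma_zero force `gamma = 0` in macrocycle 1.
#' @param release_last_two set `w_den = 0` in the final two macrocycles
#'   (requires `n_macrocycles >= 3`).
#' @param schedule an [annealing_schedule()]; default uses a 1 fs step, the
#'   stable choice for the Cartesian integrator.
#' @param selection a [selection_config()].
#' @param bfactor_mode `"none"`, `"grouped"` (two B factors per residue:
#'   main chain and side chain) or `"individual"`.
#' @param min_steps iterations of gradient-based positional minimization
#'   appended after each macrocycle's annealing (0 disables).
#' @param update_before_dynamics passed to [run_slow_cooling()].
#' @param seed master seed; all restraint-selection and velocity draws are
#'   derived from it with [derive_seed()].
#' @return an object of class `den_refinement_config`.
#' @export
refinement_config <- function(gamma = 0, w_den = 100, w_xray = "auto",
                              kappa = 0.1, n_macrocycles = 8,
                              first_cycle_gamma_zero = TRUE,
                              release_last_two = TRUE,
                              schedule = annealing_schedule(timestep = 1),
                              selection = selection_config(),
                              bfactor_mode = c("grouped", "none", "individual"),
                              min_steps = 200,
                              update_before_dynamics = FALSE,
                              seed = 1) {
  bfactor_mode <- match.arg(bfactor_mode)
  if (!(gamma >= 0 && gamma <= 1)) stop("gamma must be in [0, 1]")
  if (w_den < 0) stop("w_den must be >= 0")
  if (n_macrocycles < 1) stop("n_macrocycles must be >= 1")
  if (release_last_two && n_macrocycles < 3)
    stop("release_last_two requires n_macrocycles >= 3")
  structure(list(gamma = gamma, w_den = w_den, w_xray = w_xray, kappa = kappa,
                 n_macrocycles = as.integer(n_macrocycles),
                 first_cycle_gamma_zero = isTRUE(first_cycle_gamma_zero),
                 release_last_two = isTRUE(release_last_two),
                 schedule = schedule, selection = selection,
                 bfactor_mode = bfactor_mode, min_steps = as.integer(min_steps),
                 update_before_dynamics = isTRUE(update_before_dynamics),
                 seed = as.integer(seed)),
            class = "den_refinement_config")
}

#' Build a refinement configuration from a YAML key-value file
#'
#' Reads a flat key-value config whose keys match the arguments of
#' [refinement_config()] (plus optional `schedule:` and `selection:` blocks
#' with the arguments of [annealing_schedule()] and [selection_config()]).
#'
#' @param path YAML file path.
#' @return a [refinement_config()].
#' @export
refinement_config_from_file <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read config files")
  kv <- yaml::read_yaml(path)
  if (!is.null(kv$schedule)) kv$schedule <- do.call(annealing_schedule, kv$schedule)
  if (!is.null(kv$selection)) kv$selection <- do.call(selection_config, kv$selection)
  do.call(refinement_config, kv)
}

#' Export an annealing trace as CSV
#'
#' Writes the per-level trace of [run_slow_cooling()] (level, temperature,
#' total/stereochemical/X-ray/DEN energies) to a CSV file.
#'
#' @param trace the `trace` data.frame of a [run_slow_cooling()] result.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' Segmented rigid-body refinement
#'
#' Treats each segment (by default one per chain) as a rigid six-degree-of-
#' freedom body (rotation-vector + translation parameterization, the rotation
#' applied about the segment centroid) and jointly optimizes all poses against
#' the work-set amplitude residual. A first pass against the low-resolution
#' subset (d >= 2 d_min) widens the convergence radius before the full-data
#' polish. Internal segment geometry is preserved exactly up to the rigid
#' motion.
#'
#' @param structure starting model.
#' @param refl a [reflection_set()] with `f_obs`.
#' @param segments list of atom-index vectors partitioning the atoms; default
#'   one segment per chain.
#' @return the structure with refined segment poses.
#' @export
rigid_body_refine <- function(structure, refl, segments = NULL) {
  segments <- segments %||% chain_indices(structure)
  if (length(segments) < 1) stop("need at least one segment")
  idx_all <- sort(unname(unlist(segments)))
  if (!identical(idx_all, seq_len(n_atoms(structure))))
    stop("segments must partition the atoms (each atom in exactly one segment)")
  xyz0 <- coords(structure)
  centers <- lapply(segments, function(ix) colMeans(xyz0[ix, , drop = FALSE]))
  apply_pose <- function(par) {
    xyz <- xyz0
    for (sidx in seq_along(segments)) {
      p <- par[(6 * (sidx - 1) + 1):(6 * sidx)]
      ix <- segments[[sidx]]
      R <- rotvec_to_matrix(p[1:3])
      xyz[ix, ] <- sweep(sweep(xyz0[ix, , drop = FALSE], 2, centers[[sidx]]) %*% t(R),
                         2, centers[[sidx]] + p[4:6], "+")
    }
    xyz
  }
  work <- if (is.null(refl$is_test)) rep(TRUE, nrow(refl$hkl)) else !refl$is_test
  Mfrac <- fractionalization_matrix(structure$cell)
  W <- scattering_weights(structure, refl)
  resid_fn <- function(par, sel) {
    xfrac <- apply_pose(par) %*% t(Mfrac)
    Fc <- Mod(cpp_structure_factors(refl$hkl[sel, , drop = FALSE], xfrac,
                                    W[, sel, drop = FALSE]))
    fo <- refl$f_obs[sel]
    k <- sum(fo * Fc) / sum(Fc^2)
    sum((fo - k * Fc)^2)
  }
  par <- rep(0, 6 * length(segments))
  pscale <- rep(c(0.02, 0.02, 0.02, 0.2, 0.2, 0.2), length(segments))
  lowres <- work & refl$s <= 1 / (2 * refl$d_min)
  stages <- if (sum(lowres) >= 30) list(lowres, work) else list(work)
  conv <- 0
  for (sel in stages) {
    fit <- optim(par, resid_fn, sel = sel, method = "BFGS",
                 control = list(maxit = 200, parscale = pscale, reltol = 1e-12))
    par <- fit$par
    conv <- fit$convergence
  }
  if (conv != 0)
    warning("rigid-body optimizer did not fully converge; returning best pose")
  coords(structure) <- apply_pose(par)
  structure
}

#' Grouped or individual isotropic B-factor refinement
#'
#' Optimizes isotropic B factors against the work-set amplitude residual with
#' bound constraints `B` in `[1, 500]`. In grouped mode each residue gets two
#' B factors — one shared by its main-chain atoms (N, CA, C, O) and one by its
#' side-chain atoms — the standard parameterization when individual atomic B
#' factors would over-fit. Coordinates are untouched.
#'
#' @param structure a [den_structure()].
#' @param refl a [reflection_set()] with `f_obs`.
#' @param mode `"grouped"` or `"individual"`.
#' @return the structure with refined B factors.
#' @export
bfactor_refine <- function(structure, refl, mode = c("grouped", "individual")) {
  mode <- match.arg(mode)
  at <- structure$atoms
  group <- if (mode == "grouped") {
    main <- at$name %in% c("N", "CA", "C", "O")
    as.integer(factor(paste(at$chain, at$residue_index, ifelse(main, "m", "s"))))
  } else seq_len(nrow(at))
  ngroup <- max(group)
  Mfrac <- fractionalization_matrix(structure$cell)
  phi <- 2 * pi * (coords(structure) %*% t(Mfrac)) %*% t(refl$hkl)
  fa <- at$occ * form_factors(at$element, refl$s)
  s2 <- refl$s^2
  work <- if (is.null(refl$is_test)) rep(TRUE, nrow(refl$hkl)) else !refl$is_test
  # Atoms sharing one B factor collapse into a complex per-group partial sum
  # A_gh = sum_i fa_ih exp(i phi_ih), so each objective evaluation scales with
  # the number of groups, not atoms.
  Are <- rowsum(fa * cos(phi), group)
  Aim <- rowsum(fa * sin(phi), group)
  Aabs <- pmax(sqrt(Are^2 + Aim^2), 1e-300)
  Cg <- Are / Aabs; Sg <- Aim / Aabs
  # group-mean starting values
  b_start <- tapply(at$b, group, mean)[as.character(seq_len(ngroup))]
  memo_b <- NULL; memo <- NULL
  obj <- function(bg) {
    if (is.null(memo_b) || !identical(bg, memo_b)) {
      memo_b <<- bg
      memo <<- cpp_bfactor_residual(Aabs, Cg, Sg, s2, bg, refl$f_obs, work)
    }
    memo
  }
  fn <- function(bg) obj(bg)$energy
  gr <- function(bg) obj(bg)$grad
  fit <- optim(pmin(pmax(as.numeric(b_start), 1), 500), fn, gr,
               method = "L-BFGS-B", lower = 1, upper = 500,
               control = list(maxit = 60, factr = 1e5))
  structure$atoms$b <- fit$par[group]
  structure
}

#' Automatic X-ray weight by gradient-norm matching
#'
#' Chooses `w_xray` so that the RMS per-atom X-ray force equals the RMS
#' per-atom stereochemical force. When the model sits at a minimum of the
#' stereochemical term (as freshly idealized starting models do) the ratio at
#' the current coordinates is ill-conditioned, so the probe point is then
#' taken from a short deterministic thermal burst of stereochemistry-only
#' dynamics, mirroring how annealing programs estimate the weight along a
#' short trajectory.
#'
#' @param structure current model.
#' @param refl a [reflection_set()] with `f_obs`.
#' @param topology a [build_topology()] result.
#' @param probe `"auto"` (burst only if the current stereochemical gradient is
#'   negligible), `"current"`, or `"thermal"`.
#' @param burst_temperature,burst_steps burst parameters.
#' @param seed seed for the burst velocities.
#' @return a positive scalar weight.
#' @export
auto_weight_xray <- function(structure, refl, topology,
                             probe = c("auto", "current", "thermal"),
                             burst_temperature = 300, burst_steps = 20,
                             seed = 97) {
  probe <- match.arg(probe)
  rms_force <- function(f) sqrt(mean(rowSums(f^2)))
  xyz <- coords(structure)
  g_mm <- rms_force(geom_energy_forces(xyz, topology)$forces)
  if (probe == "thermal" || (probe == "auto" && g_mm < 1.0)) {
    st <- dynamics_state(structure)
    st <- assign_velocities(st, burst_temperature, seed)
    st <- run_md(st, burst_steps, 1,
                 function(x) geom_energy_forces(x, topology))$state
    xyz <- st$xyz
    g_mm <- rms_force(geom_energy_forces(xyz, topology)$forces)
  }
  probe_structure <- structure
  coords(probe_structure) <- xyz
  g_x <- rms_force(xray_energy_forces(probe_structure, refl, w_xray = 1)$forces)
  if (g_mm <= 0 || g_x <= 0) return(1)
  g_mm / g_x
}

# Composite target evaluator used by annealing and minimization. W (scattering
# weights) is precomputed because B factors are fixed during dynamics.
make_energy_evaluator <- function(structure, refl, topology, w_xray, w_den) {
  Mfrac <- fractionalization_matrix(structure$cell)
  Gcart <- 2 * pi * refl$hkl %*% Mfrac
  W <- scattering_weights(structure, refl)
  work <- if (is.null(refl$is_test)) rep(TRUE, nrow(refl$hkl)) else !refl$is_test
  fobs <- refl$f_obs
  hkl <- refl$hkl
  f <- function(xyz, network) {
    gm <- cpp_geom_energy_forces(xyz, topology$bonds, topology$b0, topology$kb,
                                 topology$angles, topology$a0, topology$ka,
                                 topology$rcon, topology$rfac, topology$krep,
                                 topology$excl)
    xr <- cpp_xray_energy_forces(hkl, Gcart, xyz %*% t(Mfrac), W, fobs, work,
                                 w_xray)
    r <- network$restraints
    dn <- if (nrow(r) > 0 && w_den > 0)
      cpp_den_energy_forces(r$i, r$j, r$d0, xyz, w_den)
    else list(energy = 0, forces = 0)
    list(energy = gm$energy + xr$energy + dn$energy,
         forces = gm$forces + xr$forces + dn$forces,
         e_mm = gm$energy, e_xray = xr$energy, e_den = dn$energy)
  }
  # cheap DEN-only energy used by the annealing loop for pre/post-update
  # bookkeeping (avoids a full X-ray evaluation)
  attr(f, "den_energy") <- function(xyz, network) {
    r <- network$restraints
    if (nrow(r) == 0 || w_den == 0) return(0)
    cpp_den_energy_forces(r$i, r$j, r$d0, xyz, w_den)$energy
  }
  f
}

# L-BFGS positional minimization of the composite target at fixed d0; the
# evaluator result is memoized so the paired fn/gr calls cost one evaluation.
minimize_target <- function(xyz, network, energies, maxit) {
  if (maxit <= 0) return(xyz)
  n <- nrow(xyz)
  last_p <- NULL
  last_ev <- NULL
  ev_at <- function(p) {
    if (is.null(last_p) || !identical(p, last_p)) {
      last_p <<- p
      last_ev <<- energies(matrix(p, n, 3), network)
    }
    last_ev
  }
  fn <- function(p) ev_at(p)$energy
  gr <- function(p) -as.vector(ev_at(p)$forces)
  res <- optim(as.vector(xyz), fn, gr, method = "L-BFGS-B",
               control = list(maxit = maxit, factr = 1e5))
  matrix(res$par, n, 3)
}

#' DEN-restrained simulated-annealing refinement
#'
#' The full macrocycle loop. Each macrocycle: (1) recompute `w_xray` by
#' gradient-norm matching when `w_xray = "auto"`; (2) slow-cooling annealing
#' under stereochemistry + X-ray target + DEN restraints, with the DEN
#' equilibria deformed at every temperature decrement; (3) gradient-based
#' positional minimization of the same target; (4) optional B-factor
#' refinement. Macrocycle 1 uses nondeformable restraints (`gamma = 0`) when
#' `first_cycle_gamma_zero`; the final two macrocycles run with `w_den = 0`
#' when `release_last_two`, and the coordinate drift over those released
#' cycles (RMSD between the models after macrocycles n-2 and n) is reported
#' as a convergence probe. The restraint pair list is selected once and never
#' changes within one refinement.
#'
#' @param start starting model.
#' @param reference reference model (identical atoms, same order). May equal
#'   `start`, the typical case.
#' @param refl a [reflection_set()] with `f_obs` and test flags.
#' @param config a [refinement_config()].
#' @return an object of class `den_refinement`: `model`, `r_work`, `r_free`,
#'   `geometry_score`, `drift`, per-macrocycle `trace`, `network`, `seeds`.
#' @export
run_den_refinement <- function(start, reference, refl, config = refinement_config()) {
  check_correspondence(start, reference)
  topology <- build_topology(start)
  sel_seed <- derive_seed(config$seed, 101)
  network <- select_restraints(start, reference, config$selection, sel_seed)
  model <- start
  M <- config$n_macrocycles
  trace <- data.frame(macrocycle = seq_len(M), gamma = NA_real_,
                      w_den = NA_real_, w_xray = NA_real_,
                      r_work = NA_real_, r_free = NA_real_,
                      geometry_score = NA_real_)
  vel_seeds <- integer(M)
  model_released <- NULL
  for (m in seq_len(M)) {
    gamma_m <- if (m == 1 && config$first_cycle_gamma_zero) 0 else config$gamma
    w_den_m <- if (config$release_last_two && m > M - 2) 0 else config$w_den
    w_x <- if (identical(config$w_xray, "auto")) {
      auto_weight_xray(model, refl, topology,
                       seed = derive_seed(config$seed, 300 + m))
    } else config$w_xray
    energies <- make_energy_evaluator(model, refl, topology, w_x, w_den_m)
    st <- dynamics_state(model)
    vel_seeds[m] <- derive_seed(config$seed, 200 + m)
    st <- assign_velocities(st, config$schedule$t_start, vel_seeds[m])
    sc <- tryCatch(
      run_slow_cooling(st, config$schedule, network, energies,
                       gamma = gamma_m, kappa = config$kappa,
                       update_before_dynamics = config$update_before_dynamics),
      error = function(e) {
        e$trace <- trace[seq_len(m - 1), , drop = FALSE]
        stop(e)
      })
    network <- sc$network
    xyz <- minimize_target(sc$state$xyz, network, energies, config$min_steps)
    coords(model) <- xyz
    if (config$bfactor_mode != "none")
      model <- bfactor_refine(model, refl, config$bfactor_mode)
    rf <- r_factors(refl, calc_structure_factors(model, refl))
    trace[m, 2:7] <- c(gamma_m, w_den_m, w_x, rf$r_work, rf$r_free,
                       geometry_score(coords(model), topology))
    if (config$release_last_two && m == M - 2) model_released <- model
  }
  drift <- if (!is.null(model_released))
    rmsd_xyz(coords(model_released), coords(model)) else NA_real_
  structure(list(
    model = model,
    r_work = trace$r_work[M], r_free = trace$r_free[M],
    geometry_score = trace$geometry_score[M],
    drift = drift, trace = trace, network = network,
    seeds = list(master = config$seed, selection = sel_seed,
                 velocities = vel_seeds)
  ), class = "den_refinement")
}

#' @export
print.den_refinement <- function(x, ...) {
  cat(sprintf("den_refinement: R_work %.4f  R_free %.4f  geometry %.3f",
              x$r_work, x$r_free, x$geometry_score))
  if (!is.na(x$drift)) cat(sprintf("  drift %.3f A", x$drift))
  cat("\n")
  invisible(x)
}

#' Write refinement statistics as JSON
#'
#' @param result a [run_den_refinement()] result.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_refinement_json <- function(result, path) {
  jsonlite::write_json(list(
    r_work = result$r_work, r_free = result$r_free,
    geometry_score = result$geometry_score, drift = result$drift,
    seeds = result$seeds, trace = result$trace
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
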