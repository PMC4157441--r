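test_that("rigid-body refinement is the identity at the optimum and preserves rigidity", {
  b <- make_bundle(2, 6, spacing = 9)
  refl <- make_observations(b, d_min = 6, noise_frac = 0, seed = 3)
  out <- rigid_body_refine(b, refl)
  expect_lt(denrefine:::rmsd_xyz(coords(out), coords(b)), 1e-4)
  # rigidity contract on a displaced start
  disp <- b
  xyz <- coords(b)
  ci <- chain_indices(b)
  xyz[ci$A, ] <- denrefine:::rotate_about_axis(xyz[ci$A, ], colMeans(xyz[ci$A, ]),
                                               c(0, 0, 1), 4 * pi / 180)
  coords(disp) <- xyz
  ref <- rigid_body_refine(disp, refl)
  d_in <- stats::dist(coords(disp)[ci$A, ])
  d_out <- stats::dist(coords(ref)[ci$A, ])
  expect_lt(max(abs(d_in - d_out)), 1e-7)
})

test_that("segments must partition the atom set", {
  b <- make_bundle(2, 4, spacing = 9)
  refl <- make_observations(b, d_min = 7, noise_frac = 0, seed = 1)
  expect_error(rigid_body_refine(b, refl, segments = list(1:5)), "partition")
})

test_that("grouped B refinement recovers main/side-chain B values", {
  truth <- make_helix(8)
  truth$atoms$b <- ifelse(truth$atoms$name %in% c("N", "CA", "C", "O"), 40, 80)
  refl <- make_observations(truth, d_min = 2.5, noise_frac = 0, seed = 5)
  start <- truth
  start$atoms$b <- rep(20, n_atoms(truth))
  out <- bfactor_refine(start, refl, "grouped")
  main <- out$atoms$name %in% c("N", "CA", "C", "O")
  expect_lt(max(abs(out$atoms$b[main] - 40) / 40), 0.15)
  expect_lt(max(abs(out$atoms$b[!main] - 80) / 80), 0.15)
  # coordinates untouched
  expect_identical(coords(out), coords(start))
  # correct B on self-data stays put
  out2 <- bfactor_refine(truth, refl, "grouped")
  expect_lt(max(abs(out2$atoms$b - truth$atoms$b)), 1)
})

test_that("automatic X-ray weighting matches gradient norms", {
  truth <- make_helix(6)
  start <- perturb_structure(truth, 1.0, seed = 9)
  refl <- make_observations(truth, d_min = 3.5, noise_frac = 0, seed = 2)
  topo <- build_topology(start)
  # displace so the stereochemical gradient is appreciable at the probe point
  set.seed(4)
  coords(start) <- coords(start) + matrix(rnorm(3 * n_atoms(start), 0, 0.05), ncol = 3)
  w <- auto_weight_xray(start, refl, topo, probe = "current")
  expect_gt(w, 0)
  rms <- function(f) sqrt(mean(rowSums(f^2)))
  g_mm <- rms(geom_energy_forces(start, topo)$forces)
  g_x <- rms(xray_energy_forces(start, refl, w_xray = w)$forces)
  expect_equal(g_x, g_mm, tolerance = 1e-10)
  # scaling the observations leaves the matched ratio at one
  refl10 <- refl
  refl10$f_obs <- 10 * refl10$f_obs
  w10 <- auto_weight_xray(start, refl10, topo, probe = "current")
  g_x10 <- rms(xray_energy_forces(start, refl10, w_xray = w10)$forces)
  expect_equal(g_x10 / g_mm, 1, tolerance = 1e-10)
  # doubling the force constants doubles the matched X-ray force
  topo2 <- build_topology(perturb_structure(truth, 1.0, seed = 9),
                          k_bond = 2000, k_angle = 200)
  w2 <- auto_weight_xray(start, refl, topo2, probe = "current")
  g_x2 <- rms(xray_energy_forces(start, refl, w_xray = w2)$forces)
  expect_equal(g_x2 / g_x, 2, tolerance = 1e-8)
})

test_that("refinement with w_den = 0 reduces to unrestrained annealing", {
  truth <- make_helix(6)
  start <- perturb_structure(truth, 0.8, seed = 12)
  refl <- make_observations(truth, d_min = 4, noise_frac = 0, seed = 7)
  cfg <- refinement_config(w_den = 0, n_macrocycles = 3, release_last_two = FALSE,
                           schedule = annealing_schedule(t_start = 600, dt_temp = 200,
                                                         timestep = 1),
                           min_steps = 30, bfactor_mode = "none", seed = 5)
  res <- run_den_refinement(start, start, refl, cfg)
  expect_equal(nrow(res$trace), 3)
  expect_true(all(res$trace$w_den == 0))
})

test_that("refinement is deterministic given the seed and follows the macrocycle rules", {
  truth <- make_helix(6)
  start <- perturb_structure(truth, 1.0, seed = 2)
  refl <- make_observations(truth, d_min = 4, noise_frac = 0.05, seed = 9)
  cfg <- refinement_config(gamma = 0.6, w_den = 50, n_macrocycles = 4,
                           schedule = annealing_schedule(t_start = 1000, dt_temp = 250,
                                                         timestep = 1),
                           min_steps = 30, seed = 77)
  r1 <- run_den_refinement(start, start, refl, cfg)
  r2 <- run_den_refinement(start, start, refl, cfg)
  expect_identical(r1$r_free, r2$r_free)
  expect_identical(coords(r1$model), coords(r2$model))
  # gamma = 0 in the first macrocycle, w_den = 0 in the last two
  expect_equal(r1$trace$gamma, c(0, 0.6, 0.6, 0.6))
  expect_equal(r1$trace$w_den, c(50, 50, 0, 0))
  expect_false(is.na(r1$drift))
  # restraint pair list is fixed across macrocycles (d0 evolves, pairs do not)
  net0 <- select_restraints(start, start, cfg$selection, r1$seeds$selection)
  expect_identical(net0$restraints$i, r1$network$restraints$i)
  expect_identical(net0$restraints$j, r1$network$restraints$j)
})

test_that("configuration invariants are enforced", {
  expect_error(refinement_config(gamma = 1.5), "gamma")
  expect_error(refinement_config(n_macrocycles = 2, release_last_two = TRUE),
               "release_last_two")
  expect_error(refinement_config(w_den = -1), "w_den")
})
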