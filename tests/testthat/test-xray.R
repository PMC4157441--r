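test_that("index generation equals a brute-force scan with the hemisphere rule", {
  cell <- c(20, 20, 20, 90, 90, 90)
  refl <- generate_hkl(cell, d_min = 10)
  grid <- expand.grid(h = -3:3, k = -3:3, l = -3:3)
  s <- sqrt(grid$h^2 + grid$k^2 + grid$l^2) / 20
  hemi <- grid$h > 0 | (grid$h == 0 & grid$k > 0) |
    (grid$h == 0 & grid$k == 0 & grid$l > 0)
  expected <- grid[s <= 0.1 & s > 0 & hemi, ]
  got <- as.data.frame(refl$hkl)
  names(got) <- c("h", "k", "l")
  o <- function(d) d[order(d$h, d$k, d$l), ]
  expect_equal(unname(as.matrix(o(got))), unname(as.matrix(o(expected))))
})

test_that("no reflection appears together with its Friedel mate", {
  refl <- generate_hkl(c(25, 30, 18, 90, 90, 90), d_min = 5)
  key <- apply(refl$hkl, 1, paste, collapse = ",")
  mate <- apply(-refl$hkl, 1, paste, collapse = ",")
  expect_length(intersect(key, mate), 0)
})

test_that("shrinking d_min strictly grows the index set", {
  cell <- c(30, 30, 30, 90, 90, 90)
  n8 <- nrow(generate_hkl(cell, 8)$hkl)
  n4 <- nrow(generate_hkl(cell, 4)$hkl)
  expect_gt(n4, n8)
  k8 <- apply(generate_hkl(cell, 8)$hkl, 1, paste, collapse = ",")
  k4 <- apply(generate_hkl(cell, 4)$hkl, 1, paste, collapse = ",")
  expect_true(all(k8 %in% k4))
})

test_that("a single carbon at the origin scatters with zero phase", {
  at <- data.frame(serial = 1L, name = "C", element = "C", resno = 1L,
                   residue_index = 0L, resname = "ALA", chain = "A",
                   x = 0, y = 0, z = 0, occ = 1, b = 0)
  s1 <- den_structure(at, c(20, 20, 20, 90, 90, 90))
  refl <- generate_hkl(s1$cell, 5)
  F <- calc_structure_factors(s1, refl)
  expect_lt(max(abs(Im(F))), 1e-10)
  expect_equal(Re(F), as.numeric(form_factors("C", refl$s)), tolerance = 1e-12)
})

test_that("translation by a lattice vector leaves structure factors unchanged", {
  h <- make_helix(4)
  refl <- generate_hkl(h$cell, 4)
  F0 <- calc_structure_factors(h, refl)
  h2 <- h
  coords(h2) <- sweep(coords(h), 2, h$cell[1:3], "+")
  F1 <- calc_structure_factors(h2, refl)
  expect_lt(max(Mod(F1 - F0) / Mod(F0)), 1e-9)
})

test_that("production structure factors match the independent brute-force sum", {
  h <- make_helix(4)  # 20 atoms
  refl <- generate_hkl(h$cell, 4)
  F <- calc_structure_factors(h, refl)
  Fb <- brute_force_sf(h, refl)
  expect_lt(max(Mod(F - Fb) / Mod(Fb)), 1e-8)
})

test_that("Friedel symmetry |F(-h)| = |F(h)| holds on the full sphere", {
  h <- perturbed_helix(4, sd = 0.2, seed = 2)
  refl <- generate_hkl(h$cell, 5)
  Fp <- calc_structure_factors(h, refl)
  neg <- reflection_set(h$cell, -refl$hkl, refl$d_min)
  Fm <- calc_structure_factors(h, neg)
  expect_equal(Mod(Fp), Mod(Fm), tolerance = 1e-12)
})

test_that("truth model on its own noise-free data has zero target and zero R", {
  h <- make_helix(6)
  refl <- make_observations(h, d_min = 3.5, noise_frac = 0, seed = 4)
  ev <- xray_energy_forces(h, refl)
  expect_lt(ev$energy / sum(refl$f_obs^2), 1e-10)
  expect_lt(max(abs(ev$forces)), 1e-8)
  rf <- r_factors(refl, calc_structure_factors(h, refl))
  expect_lt(rf$r_work, 1e-10)
  expect_lt(rf$r_free, 1e-10)
})

test_that("X-ray forces match the finite-difference gradient", {
  truth <- make_helix(5)
  refl <- make_observations(truth, d_min = 4, noise_frac = 0, seed = 6)
  p <- truth
  set.seed(10)
  coords(p) <- coords(truth) + matrix(rnorm(3 * n_atoms(truth), 0, 0.3), ncol = 3)
  ev <- xray_energy_forces(p, refl, w_xray = 2.5)
  fd <- fd_forces(function(x) {
    q <- p; coords(q) <- x
    xray_energy_forces(q, refl, w_xray = 2.5)$energy
  }, coords(p), step = 1e-4, atoms = 1:8)
  expect_lt(max(abs(fd - ev$forces[1:8, ]) / (abs(fd) + 1e-3)), 1e-4)
})

test_that("energy and forces are linear in the X-ray weight", {
  p <- perturbed_helix(4, sd = 0.25, seed = 3)
  refl <- make_observations(make_helix(4), d_min = 4, noise_frac = 0, seed = 1)
  e1 <- xray_energy_forces(p, refl, w_xray = 1)
  e2 <- xray_energy_forces(p, refl, w_xray = 2)
  expect_equal(e2$energy, 2 * e1$energy, tolerance = 1e-12)
  expect_equal(e2$forces, 2 * e1$forces, tolerance = 1e-12)
})

test_that("test reflections contribute nothing to energy or forces", {
  truth <- make_helix(5)
  refl <- make_observations(truth, d_min = 4, noise_frac = 0.05, seed = 8)
  p <- perturbed_helix(5, sd = 0.2, seed = 12)
  e0 <- xray_energy_forces(p, refl)
  refl2 <- refl
  set.seed(99)
  refl2$f_obs[refl2$is_test] <- refl2$f_obs[refl2$is_test] * runif(sum(refl2$is_test), 0.1, 3)
  e1 <- xray_energy_forces(p, refl2)
  expect_identical(e0$energy, e1$energy)
  expect_identical(e0$forces, e1$forces)
})

test_that("R factors are invariant to an overall scale of F_calc", {
  truth <- make_helix(5)
  refl <- make_observations(truth, d_min = 4, noise_frac = 0.1, seed = 5)
  F <- calc_structure_factors(truth, refl)
  r1 <- r_factors(refl, F)
  r2 <- r_factors(refl, 7.3 * F)
  expect_equal(r1$r_work, r2$r_work, tolerance = 1e-12)
  expect_equal(r1$r_free, r2$r_free, tolerance = 1e-12)
})

test_that("random structures give R_free near the acentric random expectation", {
  truth <- make_helix(6)
  refl <- make_observations(truth, d_min = 4, noise_frac = 0, seed = 7)
  set.seed(123)
  rvals <- replicate(5, {
    rnd <- truth
    coords(rnd) <- matrix(runif(3 * n_atoms(truth), 0, 25), ncol = 3)
    r_factors(refl, calc_structure_factors(rnd, refl))$r_free
  })
  expect_gt(mean(rvals), 0.45)
  expect_lt(mean(rvals), 0.70)
})

test_that("test-set assignment is seeded, bounded and validated", {
  refl <- generate_hkl(c(40, 40, 40, 90, 90, 90), 4)
  refl$f_obs <- rep(1, nrow(refl$hkl))
  n <- nrow(refl$hkl)
  expect_gt(n, 900)
  a <- assign_test_set(refl, 0.10, seed = 11)
  expect_true(sum(a$is_test) >= qbinom(0.005, n, 0.1) &&
                sum(a$is_test) <= qbinom(0.995, n, 0.1))
  b <- assign_test_set(refl, 0.10, seed = 11)
  expect_identical(a$is_test, b$is_test)
  expect_error(assign_test_set(refl, 0.6, 1), "fraction")
  expect_error(assign_test_set(refl, 0, 1), "fraction")
})

test_that("reflection file round trip is exact", {
  truth <- make_helix(5)
  refl <- make_observations(truth, d_min = 4, noise_frac = 0.05, seed = 14)
  tf <- withr::local_tempfile(fileext = ".hkl")
  write_reflections(refl, tf)
  back <- read_reflections(tf)
  expect_identical(back$hkl, refl$hkl)
  expect_identical(back$f_obs, refl$f_obs)
  expect_identical(back$is_test, refl$is_test)
  expect_equal(back$cell, refl$cell)
  expect_equal(back$d_min, refl$d_min)
})

test_that("degenerate X-ray inputs raise the documented errors", {
  h <- make_helix(4)
  refl <- generate_hkl(h$cell, 5)
  expect_error(xray_energy_forces(h, refl), "no observed")
  refl$f_obs <- rep(0, nrow(refl$hkl))
  expect_error(xray_energy_forces(h, refl), "zero")
  refl$f_obs <- rep(1, nrow(refl$hkl))
  expect_error(r_factors(refl, calc_structure_factors(h, refl)), "test set")
  expect_error(generate_hkl(c(5, 5, 5, 90, 90, 90), 10), "empty")
})
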