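test_that("helix construction gives the expected atoms and regular geometry", {
  h <- make_helix(10)
  expect_equal(n_atoms(h), 50)
  expect_equal(n_residues(h), 10)
  ca <- coords(h)[h$atoms$name == "CA", ]
  d <- sqrt(rowSums(diff(ca)^2))
  expect_lt(diff(range(d)), 0.05)   # all consecutive CA-CA distances equal
  expect_equal(mean(d), 3.8, tolerance = 0.05)
  # alpha-helical hydrogen-bonding geometry: O(i)..N(i+4) close
  xyz <- coords(h)
  Opos <- xyz[h$atoms$name == "O", ]
  Npos <- xyz[h$atoms$name == "N", ]
  on <- sqrt(rowSums((Opos[1:6, ] - Npos[5:10, ])^2))
  expect_true(all(on < 3.5))
})

test_that("helix backbone torsions are alpha-helical and chirality is L", {
  h <- make_helix(4)
  xyz <- coords(h)
  g <- function(i, n) xyz[which(h$atoms$resno == i & h$atoms$name == n), ]
  phi <- dihedral_deg(g(1, "C"), g(2, "N"), g(2, "CA"), g(2, "C"))
  psi <- dihedral_deg(g(2, "N"), g(2, "CA"), g(2, "C"), g(3, "N"))
  expect_equal(phi, -57, tolerance = 0.1)
  expect_equal(psi, -47, tolerance = 0.1)
  improper <- dihedral_deg(g(2, "N"), g(2, "C"), g(2, "CA"), g(2, "CB"))
  expect_gt(improper, 0)  # L-amino acid branch
})

test_that("helix sits in a padded P1 box", {
  h <- make_helix(12)
  xyz <- coords(h)
  expect_true(all(apply(xyz, 2, min) >= 9.99))
  expect_true(all(h$cell[1:3] - apply(xyz, 2, max) >= 9.99))
})

test_that("bundle construction places distinct parallel chains on a circle", {
  b <- make_bundle(3, 8, spacing = 10)
  expect_equal(n_atoms(b), 120)
  expect_identical(sort(unique(b$atoms$chain)), c("A", "B", "C"))
  xyz <- coords(b)
  ci <- chain_indices(b)
  centers <- t(vapply(ci, function(ix) colMeans(xyz[ix, ]), numeric(3)))
  expect_equal(sqrt(sum((centers[1, ] - centers[2, ])^2)), 10, tolerance = 1e-6)
  # minimum inter-chain distance bounded below by spacing minus helix radius
  dAB <- min(as.matrix(stats::dist(xyz))[ci$A, ci$B])
  expect_gt(dAB, 10 - 7)
  expect_error(make_bundle(3, 8, spacing = 3), "spacing")
})

test_that("torsion perturbation hits the target RMSD and keeps geometry ideal", {
  h <- make_helix(20)
  expect_identical(perturb_structure(h, 0, seed = 1), h)
  p <- perturb_structure(h, 2.0, seed = 31, mode = "torsion")
  r <- denrefine:::rmsd_xyz(coords(p), coords(h))
  expect_gte(r, 1.8)
  expect_lte(r, 2.2)
  topo <- build_topology(h)
  d <- sqrt(rowSums((coords(p)[topo$bonds[, 1], ] -
                       coords(p)[topo$bonds[, 2], ])^2))
  expect_lt(sqrt(mean((d - topo$b0)^2)), 0.02)
})

test_that("smooth cartesian perturbation is calibrated and re-idealized", {
  h <- make_helix(12)
  p <- perturb_structure(h, 1.5, seed = 7, mode = "cartesian_smooth")
  r <- denrefine:::rmsd_xyz(coords(p), coords(h))
  expect_gte(r, 1.35)
  expect_lte(r, 1.65)
  topo <- build_topology(h)
  d <- sqrt(rowSums((coords(p)[topo$bonds[, 1], ] -
                       coords(p)[topo$bonds[, 2], ])^2))
  expect_lt(sqrt(mean((d - topo$b0)^2)), 0.02)
  expect_error(perturb_structure(make_helix(4), 50, seed = 1), "calibration")
})

test_that("perturbation is deterministic by seed", {
  h <- make_helix(10)
  a <- perturb_structure(h, 1.2, seed = 4)
  b <- perturb_structure(h, 1.2, seed = 4)
  expect_identical(coords(a), coords(b))
})

test_that("synthetic observations behave as prescribed by the noise model", {
  truth <- make_helix(8)
  r0 <- make_observations(truth, d_min = 3.5, noise_frac = 0, seed = 5)
  expect_equal(r0$f_obs, Mod(calc_structure_factors(truth, r0)), tolerance = 1e-14)
  expect_lt(r_factors(r0, calc_structure_factors(truth, r0))$r_work, 1e-12)
  r5 <- make_observations(truth, d_min = 3.5, noise_frac = 0.05, seed = 5)
  rw <- r_factors(r5, calc_structure_factors(truth, r5))$r_work
  expect_gt(rw, 0.02)   # mean |N(0,1)| * 0.05 ~ 0.04
  expect_lt(rw, 0.06)
})

test_that("benchmark scenarios are reproducible and correctly parameterized", {
  sc <- make_benchmark_scenario("lowres_helix", seed = 3)
  sc2 <- make_benchmark_scenario("lowres_helix", seed = 3)
  expect_identical(coords(sc$start), coords(sc2$start))
  expect_identical(sc$refl$f_obs, sc2$refl$f_obs)
  r <- denrefine:::rmsd_xyz(coords(sc$start), coords(sc$truth))
  expect_gte(r, 2.25)
  expect_lte(r, 2.75)
  expect_equal(sc$refl$d_min, 3.5)
  expect_identical(coords(sc$reference), coords(sc$start))
})

test_that("the very-low-resolution bundle preset copies its stated constants", {
  sc <- make_benchmark_scenario("verylow_bundle", seed = 2)
  expect_equal(sc$refl$d_min, 7.4)
  expect_true(sc$selection$allow_inter_chain)
  expect_equal(length(chain_indices(sc$start)), 3)
  expect_equal(sc$provenance$total_rmsd,
               denrefine:::rmsd_xyz(coords(sc$start), coords(sc$truth)))
  expect_gt(sc$provenance$total_rmsd, 3.0)
})

test_that("the register-shift preset threads a window off by one residue", {
  sc <- make_benchmark_scenario("register_shift", seed = 1)
  expect_identical(coords(sc$reference), coords(sc$truth))
  expect_gt(sc$provenance$start_rmsd, 0.5)
  # every scenario is directly consumable by the refinement entry point
  expect_silent(denrefine:::check_correspondence(sc$start, sc$reference))
  expect_true(sum(sc$refl$is_test) >= 1)
})
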