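test_that("restraint selection equals brute-force enumeration of eligible pairs", {
  h <- make_helix(5)
  n_elig_all <- function(s, cfg) {
    xyz <- coords(s)
    at <- s$atoms
    pairs <- t(combn(n_atoms(s), 2))
    d <- sqrt(rowSums((xyz[pairs[, 1], ] - xyz[pairs[, 2], ])^2))
    sep <- abs(at$residue_index[pairs[, 1]] - at$residue_index[pairs[, 2]])
    keep <- d >= cfg$d_lo & d <= cfg$d_hi & sep <= cfg$seq_sep_hi &
      at$chain[pairs[, 1]] == at$chain[pairs[, 2]]
    pairs[keep, , drop = FALSE]
  }
  cfg <- selection_config(n_restraints = 10000)
  expected <- n_elig_all(h, cfg)
  net <- select_restraints(h, h, cfg, seed = 5)
  got <- net$restraints[order(net$restraints$i, net$restraints$j), c("i", "j")]
  exp_sorted <- expected[order(expected[, 1], expected[, 2]), , drop = FALSE]
  expect_equal(unname(as.matrix(got)), unname(exp_sorted))
})

test_that("inter-chain pairs are excluded unless explicitly allowed", {
  b <- make_bundle(2, 6, spacing = 8)
  net <- select_restraints(b, b, selection_config(n_restraints = 5000), seed = 2)
  ch <- b$atoms$chain
  expect_true(all(ch[net$restraints$i] == ch[net$restraints$j]))
  net2 <- select_restraints(b, b,
    selection_config(allow_inter_chain = TRUE, seq_sep_hi = Inf,
                     n_restraints = 5000), seed = 2)
  expect_gt(sum(ch[net2$restraints$i] != ch[net2$restraints$j]), 0)
})

test_that("selection is deterministic by seed and respects all config bounds", {
  h <- make_helix(8)
  cfg <- selection_config(d_lo = 4, d_hi = 12, seq_sep_lo = 1, seq_sep_hi = 6)
  n1 <- select_restraints(h, h, cfg, seed = 42)
  n2 <- select_restraints(h, h, cfg, seed = 42)
  expect_identical(n1$restraints, n2$restraints)
  n3 <- select_restraints(h, h, cfg, seed = 43)
  expect_false(identical(n1$restraints, n3$restraints))
  # re-check every emitted pair against the reference structure
  at <- h$atoms
  r <- n1$restraints
  d_ref_check <- sqrt(rowSums((coords(h)[r$i, ] - coords(h)[r$j, ])^2))
  expect_true(all(d_ref_check >= 4 & d_ref_check <= 12))
  sep <- abs(at$residue_index[r$i] - at$residue_index[r$j])
  expect_true(all(sep >= 1 & sep <= 6))
  expect_false(any(duplicated(paste(pmin(r$i, r$j), pmax(r$i, r$j)))))
})

test_that("d0 comes from the starting model and d_ref from the reference", {
  ref <- make_helix(6)
  start <- ref
  set.seed(3)
  coords(start) <- coords(ref) + matrix(rnorm(3 * n_atoms(ref), 0, 0.2), ncol = 3)
  net <- select_restraints(start, ref, selection_config(), seed = 1)
  r <- net$restraints
  d_start <- sqrt(rowSums((coords(start)[r$i, ] - coords(start)[r$j, ])^2))
  d_ref <- sqrt(rowSums((coords(ref)[r$i, ] - coords(ref)[r$j, ])^2))
  expect_equal(r$d0, d_start)
  expect_equal(r$d_ref, d_ref)
})

test_that("selection errors are raised for degenerate inputs", {
  h <- make_helix(4)
  b <- make_bundle(2, 4)
  expect_error(select_restraints(h, b, selection_config(), 1), "correspondence")
  expect_error(select_restraints(h, h, selection_config(d_lo = 40, d_hi = 50), 1),
               "no eligible")
})

test_that("DEN energy and forces follow the harmonic definition", {
  h <- make_helix(6)
  net <- select_restraints(h, h, selection_config(), seed = 1)
  # at the starting model d = d0 everywhere: zero energy, zero force
  ev <- den_energy_forces(coords(h), net, 100)
  expect_equal(ev$energy, 0, tolerance = 1e-12)
  expect_lt(max(abs(ev$forces)), 1e-10)
  # single restraint, d = 4, d0 = 3, w = 100 -> energy exactly 100
  net1 <- net
  net1$restraints <- data.frame(i = 1L, j = 2L, d0 = 3, d_ref = 3)
  xyz <- matrix(0, 2, 3); xyz[2, 1] <- 4
  ev1 <- den_energy_forces(xyz, net1, 100)
  expect_equal(ev1$energy, 100)
  # force on unrestrained atoms is zero
  p <- perturbed_helix(6)
  netp <- select_restraints(h, h, selection_config(n_restraints = 5), seed = 7)
  evp <- den_energy_forces(coords(p), netp, 10)
  touched <- unique(c(netp$restraints$i, netp$restraints$j))
  expect_true(all(abs(evp$forces[-touched, ]) == 0))
})

test_that("DEN forces match the finite-difference gradient", {
  p <- perturbed_helix(6, sd = 0.3, seed = 21)
  h <- make_helix(6)
  net <- select_restraints(h, h, selection_config(), seed = 9)
  ev <- den_energy_forces(coords(p), net, 30)
  num <- fd_forces(function(x) den_energy_forces(x, net, 30)$energy,
                   coords(p), atoms = 1:10)
  expect_lt(max(abs(num - ev$forces[1:10, ]) / (abs(num) + 1e-4)), 1e-5)
})

test_that("coincident restrained atoms raise a singular-geometry error", {
  net <- structure(list(restraints = data.frame(i = 1L, j = 2L, d0 = 3, d_ref = 3)),
                   class = "den_network")
  xyz <- matrix(0, 2, 3)
  expect_error(den_energy_forces(xyz, net, 1), "singular|coincident")
})

test_that("equilibrium update follows the deformation equation exactly", {
  h <- make_helix(8)
  net <- select_restraints(h, h, selection_config(), seed = 3)
  xyz <- coords(h)
  # fixed point: d = d0 = d_ref stays put
  up <- update_equilibrium(net, xyz, gamma = 0.5, kappa = 0.1)
  expect_equal(up$restraints$d0, net$restraints$d0, tolerance = 1e-14)

  # gamma = 0, frozen model: geometric decay |d0(t) - d_ref| = (1-k)^t |d0(0) - d_ref|
  net0 <- net
  net0$restraints$d0 <- net$restraints$d_ref + 1.5
  dev0 <- 1.5
  cur <- net0
  for (t in 1:7) {
    cur <- update_equilibrium(cur, xyz, gamma = 0, kappa = 0.1)
    expect_equal(cur$restraints$d0 - cur$restraints$d_ref,
                 rep(0.9^t * dev0, nrow(cur$restraints)), tolerance = 1e-12)
  }

  # gamma = 1: update independent of the reference distances
  na <- net; na$restraints$d_ref <- net$restraints$d_ref + 5
  nb <- net; nb$restraints$d_ref <- net$restraints$d_ref - 2
  pa <- perturbed_helix(8, seed = 4)
  ua <- update_equilibrium(na, coords(pa), gamma = 1, kappa = 0.1)
  ub <- update_equilibrium(nb, coords(pa), gamma = 1, kappa = 0.1)
  expect_identical(ua$restraints$d0, ub$restraints$d0)

  # linearity in gamma: update(g) = (1-g) update(0) + g update(1)
  g <- 0.37
  u0 <- update_equilibrium(net0, coords(pa), gamma = 0, kappa = 0.1)
  u1 <- update_equilibrium(net0, coords(pa), gamma = 1, kappa = 0.1)
  ug <- update_equilibrium(net0, coords(pa), gamma = g, kappa = 0.1)
  expect_equal(ug$restraints$d0,
               (1 - g) * u0$restraints$d0 + g * u1$restraints$d0,
               tolerance = 1e-12)
})

test_that("parameter bounds on gamma and kappa are enforced", {
  h <- make_helix(3)
  net <- select_restraints(h, h, selection_config(), 1)
  expect_error(update_equilibrium(net, coords(h), gamma = -0.1), "gamma")
  expect_error(update_equilibrium(net, coords(h), gamma = 1.1), "gamma")
  expect_error(update_equilibrium(net, coords(h), gamma = 0.5, kappa = 0), "kappa")
})

test_that("iterating the update at frozen coordinates converges to the fixed point", {
  h <- make_helix(6)
  p <- perturbed_helix(6, sd = 0.4, seed = 31)
  net <- select_restraints(h, h, selection_config(), seed = 13)
  xyz <- coords(p)
  d <- sqrt(rowSums((xyz[net$restraints$i, ] - xyz[net$restraints$j, ])^2))
  for (g in c(0, 0.3, 1)) {
    cur <- net
    for (t in 1:300) cur <- update_equilibrium(cur, xyz, gamma = g, kappa = 0.1)
    dstar <- g * d + (1 - g) * net$restraints$d_ref
    expect_lt(max(abs(cur$restraints$d0 - dstar)), 1e-10)
    if (g == 1) {
      ev <- den_energy_forces(xyz, cur, 100)
      expect_lt(ev$energy, 1e-18)
      expect_lt(max(abs(ev$forces)), 1e-10)
    }
  }
})

test_that("restraint TSV round trip reproduces the network", {
  h <- make_helix(7)
  net <- select_restraints(h, h, selection_config(), seed = 6)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_restraints(net, h, tf)
  back <- read_restraints(tf, h)
  expect_equal(back$restraints$i, net$restraints$i)
  expect_equal(back$restraints$j, net$restraints$j)
  expect_equal(back$restraints$d0, net$restraints$d0)
  expect_equal(back$restraints$d_ref, net$restraints$d_ref)
})
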