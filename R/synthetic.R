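# Ideal alanine geometry used by the builders (bond lengths in Angstrom,
# angles in degrees).
.ala_geom <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231, b_ca_cb = 1.521,
  a_c_n_ca = 121.7, a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_ca_c_o = 120.8,
  a_n_ca_cb = 110.4, a_c_ca_cb = 110.5
)

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

# Natural-extension (NeRF) placement: position D given A-B-C, the C-D bond
# length, the B-C-D angle and the A-B-C-D torsion (radians).
place_atom <- function(A, B, C, bond, angle, torsion) {
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  n <- cross3(B - A, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d <- c(-bond * cos(angle), bond * sin(angle) * cos(torsion),
         -bond * sin(angle) * sin(torsion))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# Tetrahedral branch placement: unit direction from apex making the given
# angles with the two reference directions; `sign` picks the mirror branch
# (chirality).
place_branch <- function(apex, ref1, ref2, bond, ang1, ang2, sign = 1) {
  a <- ref1 - apex; a <- a / sqrt(sum(a^2))
  b <- ref2 - apex; b <- b / sqrt(sum(b^2))
  ab <- sum(a * b)
  sol <- solve(matrix(c(1, ab, ab, 1), 2, 2), c(cos(ang1), cos(ang2)))
  perp <- cross3(a, b); perp <- perp / sqrt(sum(perp^2))
  g2 <- 1 - (sol[1]^2 + sol[2]^2 + 2 * sol[1] * sol[2] * ab)
  g <- sqrt(max(g2, 0))
  u <- sol[1] * a + sol[2] * b + sign * g * perp
  apex + bond * u / sqrt(sum(u^2))
}

# Raw (unboxed) ideal poly-alanine helix atom table.
build_helix_atoms <- function(n_residues, chain_id = "A", b_factor = 20,
                              phi = -57, psi = -47) {
  g <- .ala_geom
  d2r <- pi / 180
  Np <- matrix(NA_real_, n_residues, 3)
  CAp <- matrix(NA_real_, n_residues, 3)
  Cp <- matrix(NA_real_, n_residues, 3)
  Np[1, ] <- c(0, 0, 0)
  CAp[1, ] <- c(g$b_n_ca, 0, 0)
  Cp[1, ] <- CAp[1, ] + g$b_ca_c *
    c(-cos(g$a_n_ca_c * d2r), sin(g$a_n_ca_c * d2r), 0)
  for (i in seq_len(n_residues)[-1]) {
    Np[i, ] <- place_atom(Np[i - 1, ], CAp[i - 1, ], Cp[i - 1, ],
                          g$b_c_n, g$a_ca_c_n * d2r, psi * d2r)
    CAp[i, ] <- place_atom(CAp[i - 1, ], Cp[i - 1, ], Np[i, ],
                           g$b_n_ca, g$a_c_n_ca * d2r, pi)
    Cp[i, ] <- place_atom(Cp[i - 1, ], Np[i, ], CAp[i, ],
                          g$b_ca_c, g$a_n_ca_c * d2r, phi * d2r)
  }
  rows <- vector("list", n_residues)
  for (i in seq_len(n_residues)) {
    O <- place_atom(Np[i, ], CAp[i, ], Cp[i, ], g$b_c_o, g$a_ca_c_o * d2r,
                    (psi + 180) * d2r)
    CB <- place_branch(CAp[i, ], Np[i, ], Cp[i, ], g$b_ca_cb,
                       g$a_n_ca_cb * d2r, g$a_c_ca_cb * d2r, sign = -1)
    xyz <- rbind(Np[i, ], CAp[i, ], Cp[i, ], O, CB)
    rows[[i]] <- data.frame(
      name = c("N", "CA", "C", "O", "CB"),
      element = c("N", "C", "C", "O", "C"),
      resno = i, residue_index = i - 1L, resname = "ALA", chain = chain_id,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occ = 1, b = b_factor, stringsAsFactors = FALSE
    )
  }
  at <- do.call(rbind, rows)
  at$serial <- seq_len(nrow(at))
  rownames(at) <- NULL
  at[, c("serial", "name", "element", "resno", "residue_index", "resname",
         "chain", "x", "y", "z", "occ", "b")]
}

# Center an atom table in a padded orthorhombic P1 box.
box_structure <- function(atoms, margin = 10) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  cell <- default_cell(xyz, margin)
  ctr <- (apply(xyz, 2, min) + apply(xyz, 2, max)) / 2
  xyz <- sweep(xyz, 2, ctr) + matrix(cell[1:3] / 2, nrow(xyz), 3, byrow = TRUE)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  den_structure(atoms, cell)
}

#' Ideal poly-alanine alpha-helix
#'
#' Builds an ideal helix (phi = -57, psi = -47 degrees, standard peptide
#' geometry, heavy atoms only: N, CA, C, O, CB per residue) centered in a
#' padded orthorhombic P1 box.
#'
#' @param n_residues number of residues (>= 2).
#' @param chain_id single-character chain identifier.
#' @param b_factor uniform isotropic B (Angstrom^2).
#' @param margin box padding (Angstrom, >= 10 keeps reflection counts at
#'   desk scale).
#' @return a [den_structure()].
#' @export
make_helix <- function(n_residues, chain_id = "A", b_factor = 20, margin = 10) {
  stopifnot(n_residues >= 2)
  box_structure(build_helix_atoms(n_residues, chain_id, b_factor), margin)
}

#' Parallel helix bundle
#'
#' Parallel copies of [make_helix()] with their centroids on a circle whose
#' adjacent-center spacing is `spacing`, one chain id per copy — the
#' multi-chain fixture for inter-chain restraint and rigid-body tests.
#'
#' @param n_chains number of chains (>= 2).
#' @param n_residues residues per chain.
#' @param spacing adjacent-center spacing (Angstrom, > 4).
#' @param b_factor uniform isotropic B.
#' @param margin box padding.
#' @return a [den_structure()].
#' @export
make_bundle <- function(n_chains, n_residues, spacing = 10, b_factor = 20,
                        margin = 10) {
  stopifnot(n_chains >= 2)
  if (spacing < 4) stop("parameter error: spacing < 4 A would clash the chains")
  base <- build_helix_atoms(n_residues, "A", b_factor)
  xyz <- as.matrix(base[, c("x", "y", "z")])
  ca <- xyz[base$name == "CA", , drop = FALSE]
  axis <- ca[nrow(ca), ] - ca[1, ]; axis <- axis / sqrt(sum(axis^2))
  e1 <- cross3(axis, c(0, 0, 1))
  if (sum(e1^2) < 1e-6) e1 <- cross3(axis, c(0, 1, 0))
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(axis, e1)
  radius <- spacing / (2 * sin(pi / n_chains))
  ctr <- colMeans(xyz)
  rows <- vector("list", n_chains)
  for (kc in seq_len(n_chains)) {
    th <- 2 * pi * (kc - 1) / n_chains
    offset <- radius * (cos(th) * e1 + sin(th) * e2)
    at <- base
    at$chain <- LETTERS[kc]
    at$x <- xyz[, 1] - ctr[1] + offset[1]
    at$y <- xyz[, 2] - ctr[2] + offset[2]
    at$z <- xyz[, 3] - ctr[3] + offset[3]
    rows[[kc]] <- at
  }
  at <- do.call(rbind, rows)
  at$serial <- seq_len(nrow(at))
  rownames(at) <- NULL
  box_structure(at, margin)
}

# Torsion kicks: rotate the downstream part of each chain about the phi and
# psi axes by amp * z (z drawn once per call from the seed).
apply_torsion_kicks <- function(structure, amp, z) {
  at <- structure$atoms
  xyz <- coords(structure)
  ki <- 0
  for (ch in unique(at$chain)) {
    cidx <- which(at$chain == ch)
    resids <- sort(unique(at$residue_index[cidx]))
    for (r in resids) {
      res_atoms <- cidx[at$residue_index[cidx] == r]
      nm <- at$name[res_atoms]
      Npos <- xyz[res_atoms[nm == "N"], ]
      CApos <- xyz[res_atoms[nm == "CA"], ]
      downstream <- cidx[at$residue_index[cidx] > r]
      # phi: about N-CA, moves C/O/CB of residue r and everything after
      ki <- ki + 1
      rot <- c(res_atoms[nm %in% c("C", "O", "CB")], downstream)
      xyz[rot, ] <- rotate_about_axis(xyz[rot, , drop = FALSE], Npos,
                                      CApos - Npos, amp * z[ki])
      # psi: about CA-C, moves O of residue r and everything after
      Cpos <- xyz[res_atoms[nm == "C"], ]
      ki <- ki + 1
      rot <- c(res_atoms[nm == "O"], downstream)
      xyz[rot, ] <- rotate_about_axis(xyz[rot, , drop = FALSE], CApos,
                                      Cpos - CApos, amp * z[ki])
    }
  }
  coords(structure) <- xyz
  structure
}

# Smooth random displacement field: a few low-frequency vector waves.
apply_smooth_field <- function(structure, amp, waves) {
  xyz <- coords(structure)
  disp <- matrix(0, nrow(xyz), 3)
  for (w in waves) {
    phase <- 2 * pi * (xyz %*% w$u) / w$lambda + w$theta
    disp <- disp + amp * sin(as.numeric(phase)) %o% w$e
  }
  coords(structure) <- xyz + disp
  structure
}

#' Perturb a structure to a prescribed RMSD
#'
#' Generates a starting model a controlled distance away from the input, the
#' synthetic analogue of perturbing a high-resolution structure by
#' unrestrained dynamics. `"torsion"` mode applies random backbone phi/psi
#' kicks propagated down-chain (local covalent geometry is preserved
#' exactly); `"cartesian_smooth"` applies a smooth low-frequency random
#' displacement field. The kick amplitude is calibrated by bisection until
#' the coordinate RMSD (no superposition) is within 10 percent of
#' `target_rmsd`; the bonded geometry is then re-idealized by minimizing the
#' stereochemical term built from the unperturbed input.
#'
#' @param structure input model.
#' @param target_rmsd target coordinate RMSD (Angstrom).
#' @param seed integer seed.
#' @param mode `"torsion"` or `"cartesian_smooth"`.
#' @return the perturbed [den_structure()].
#' @export
perturb_structure <- function(structure, target_rmsd, seed = 1,
                              mode = c("torsion", "cartesian_smooth")) {
  mode <- match.arg(mode)
  stopifnot(target_rmsd >= 0)
  if (target_rmsd == 0) return(structure)
  xyz0 <- coords(structure)
  if (mode == "torsion") {
    z <- with_seed(seed, rnorm(2 * n_residues(structure) + 2))
    deform <- function(a) apply_torsion_kicks(structure, a, z)
    amp <- 0.05
  } else {
    waves <- with_seed(seed, lapply(1:4, function(k) {
      u <- rnorm(3); e <- rnorm(3)
      list(u = u / sqrt(sum(u^2)), e = e / sqrt(sum(e^2)),
           lambda = runif(1, 15, 40), theta = runif(1, 0, 2 * pi))
    }))
    deform <- function(a) apply_smooth_field(structure, a, waves)
    amp <- target_rmsd / 2  # displacement is linear in amplitude
  }
  rms_at <- function(a) rmsd_xyz(coords(deform(a)), xyz0)
  # bracket the target, then bisect
  iter <- 0
  while (rms_at(amp) < target_rmsd) {
    amp <- amp * 2
    iter <- iter + 1
    if (iter > 40) stop("calibration error: target RMSD unreachable")
  }
  lo <- 0; hi <- amp
  for (iter in seq_len(60)) {
    mid <- (lo + hi) / 2
    r <- rms_at(mid)
    if (abs(r - target_rmsd) <= 0.08 * target_rmsd) { hi <- mid; break }
    if (r > target_rmsd) hi <- mid else lo <- mid
  }
  out <- deform(hi)
  topo <- build_topology(structure)
  coords(out) <- minimize_geometry(coords(out), topo, maxit = 400)
  achieved <- rmsd_xyz(coords(out), xyz0)
  if (abs(achieved - target_rmsd) > 0.1 * target_rmsd)
    stop(sprintf("calibration error: achieved RMSD %.2f A for target %.2f A",
                 achieved, target_rmsd))
  out
}

#' Synthetic observed amplitudes from a known structure
#'
#' Computes |F| from the given "true" structure to the stated resolution
#' limit, applies multiplicative Gaussian noise
#' `f_obs = |F| (1 + eps), eps ~ N(0, noise_frac)` clipped at zero, and
#' assigns cross-validation flags.
#'
#' @param truth the true structure.
#' @param d_min resolution limit (Angstrom).
#' @param noise_frac relative amplitude noise (0 for noise-free data).
#' @param test_fraction test-set fraction.
#' @param seed integer seed.
#' @return a [reflection_set()] with `f_obs`, `sigma` and `is_test`.
#' @export
make_observations <- function(truth, d_min, noise_frac = 0,
                              test_fraction = 0.10, seed = 1) {
  stopifnot(d_min > 0, noise_frac >= 0)
  refl <- generate_hkl(truth$cell, d_min)
  famp <- Mod(calc_structure_factors(truth, refl))
  eps <- if (noise_frac > 0)
    with_seed(derive_seed(seed, 1), rnorm(length(famp), 0, noise_frac))
  else 0
  refl$f_obs <- pmax(famp * (1 + eps), 0)
  refl$sigma <- noise_frac * famp
  assign_test_set(refl, test_fraction, derive_seed(seed, 2))
}

#' Benchmark scenarios
#'
#' Self-contained test problems mirroring the published refinement
#' experiments at desk scale:
#' \describe{
#'   \item{lowres_helix}{20-residue helix; start (= reference) perturbed to
#'     2.5 Angstrom RMSD; amplitudes to 3.5 Angstrom with 5 percent noise.
#'     The large-conformational-change setting.}
#'   \item{verylow_bundle}{3 x 12-residue helix bundle; chains rigidly
#'     displaced (about 5 degrees / 2 Angstrom each) then torsion-perturbed
#'     to about 4 Angstrom total; amplitudes truncated to 7.4 Angstrom;
#'     restraint selection with inter-chain pairs enabled and no
#'     sequence-separation limit. The very-low-resolution multi-chain
#'     setting.}
#'   \item{register_shift}{14-residue helix whose start threads a 6-residue
#'     window off by one residue; the reference is the ideal helix (a
#'     reference better than the start); noise-free amplitudes to
#'     3.0 Angstrom.}
#' }
#'
#' @param preset scenario name.
#' @param seed integer seed; every random ingredient derives from it.
#' @return an object of class `den_scenario`: `truth`, `start`, `reference`,
#'   `refl`, `selection`, `provenance`.
#' @export
make_benchmark_scenario <- function(preset = c("lowres_helix", "verylow_bundle",
                                               "register_shift"), seed = 1) {
  preset <- match.arg(preset)
  if (preset == "lowres_helix") {
    truth <- make_helix(20)
    start <- perturb_structure(truth, 2.5, derive_seed(seed, 11), "torsion")
    refl <- make_observations(truth, d_min = 3.5, noise_frac = 0.05,
                              test_fraction = 0.10, seed = derive_seed(seed, 12))
    sel <- selection_config()
    reference <- start
    prov <- list(preset = preset, seed = seed, target_rmsd = 2.5, d_min = 3.5,
                 noise_frac = 0.05)
  } else if (preset == "verylow_bundle") {
    truth <- make_bundle(3, 12, spacing = 10)
    displaced <- truth
    xyz <- coords(truth)
    dirs <- with_seed(derive_seed(seed, 21), matrix(rnorm(18), 6, 3))
    ci <- chain_indices(truth)
    for (kc in seq_along(ci)) {
      ix <- ci[[kc]]
      ctr <- colMeans(xyz[ix, , drop = FALSE])
      ax <- dirs[2 * kc - 1, ]
      tr <- dirs[2 * kc, ]; tr <- 2 * tr / sqrt(sum(tr^2))
      xyz[ix, ] <- sweep(rotate_about_axis(xyz[ix, , drop = FALSE], ctr, ax,
                                           5 * pi / 180), 2, tr, "+")
    }
    coords(displaced) <- xyz
    rigid_rmsd <- rmsd_xyz(coords(displaced), coords(truth))
    resid_target <- sqrt(max(16 - rigid_rmsd^2, 1))
    start <- perturb_structure(displaced, resid_target, derive_seed(seed, 22),
                               "torsion")
    refl <- make_observations(truth, d_min = 7.4, noise_frac = 0.05,
                              test_fraction = 0.10, seed = derive_seed(seed, 23))
    sel <- selection_config(allow_inter_chain = TRUE, seq_sep_hi = Inf)
    reference <- start
    prov <- list(preset = preset, seed = seed, rigid_rmsd = rigid_rmsd,
                 total_rmsd = rmsd_xyz(coords(start), coords(truth)),
                 d_min = 7.4, noise_frac = 0.05)
  } else {
    n_res <- 14
    truth <- make_helix(n_res)
    at <- truth$atoms
    xyz <- coords(truth)
    window <- 4:9  # 0-based residue indices threaded one residue forward
    for (r in window) {
      to <- which(at$residue_index == r)
      from <- which(at$residue_index == r + 1)
      # blend keeps the last shifted residue from landing exactly on its
      # unshifted neighbour; re-idealization restitches the junctions
      xyz[to, ] <- 0.8 * coords(truth)[from, , drop = FALSE] +
        0.2 * coords(truth)[to, , drop = FALSE]
    }
    start <- truth
    coords(start) <- xyz
    topo <- build_topology(truth)
    coords(start) <- minimize_geometry(coords(start), topo, maxit = 400)
    reference <- truth
    refl <- make_observations(truth, d_min = 3.0, noise_frac = 0,
                              test_fraction = 0.10, seed = derive_seed(seed, 31))
    sel <- selection_config()
    prov <- list(preset = preset, seed = seed, window = window, d_min = 3.0,
                 noise_frac = 0,
                 start_rmsd = rmsd_xyz(coords(start), coords(truth)))
  }
  structure(list(truth = truth, start = start, reference = reference,
                 refl = refl, selection = sel, provenance = prov),
            class = "den_scenario")
}

#' @export
print.den_scenario <- function(x, ...) {
  cat(sprintf("den_scenario '%s': %d atoms, %d reflections to %.1f A, start RMSD %.2f A\n",
              x$provenance$preset, n_atoms(x$truth), nrow(x$refl$hkl),
              x$refl$d_min, rmsd_xyz(coords(x$start), coords(x$truth))))
  invisible(x)
}
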