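# Shared fixtures and independent oracles for the test suite.

# Central finite-difference gradient of a scalar energy function; the oracle
# against which all analytic forces are checked.
fd_forces <- function(energy_fn, xyz, step = 1e-5, atoms = seq_len(nrow(xyz))) {
  g <- matrix(0, length(atoms), 3)
  for (a in seq_along(atoms)) {
    for (k in 1:3) {
      xp <- xyz; xp[atoms[a], k] <- xp[atoms[a], k] + step
      xm <- xyz; xm[atoms[a], k] <- xm[atoms[a], k] - step
      g[a, k] <- -(energy_fn(xp) - energy_fn(xm)) / (2 * step)
    }
  }
  g
}

# Independent brute-force structure-factor summation, written directly from
# the definition (complex exponential per atom) and sharing no code with the
# production kernel.
brute_force_sf <- function(structure, refl) {
  Mfrac <- denrefine:::fractionalization_matrix(structure$cell)
  xf <- coords(structure) %*% t(Mfrac)
  at <- structure$atoms
  ff <- form_factors(at$element, refl$s)
  vapply(seq_len(nrow(refl$hkl)), function(k) {
    w <- at$occ * ff[, k] * exp(-at$b * refl$s[k]^2 / 4)
    sum(w * exp(2i * pi * as.numeric(xf %*% refl$hkl[k, ])))
  }, complex(1))
}

# Dihedral angle (degrees) between four points.
dihedral_deg <- function(p1, p2, p3, p4) {
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  m1 <- cr(n1, b2) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# A helix mildly displaced away from its own geometry (non-zero forces
# everywhere) for gradient checks.
perturbed_helix <- function(n_res = 6, sd = 0.15, seed = 11) {
  h <- make_helix(n_res)
  set.seed(seed)
  coords(h) <- coords(h) + matrix(rnorm(3 * n_atoms(h), 0, sd), ncol = 3)
  h
}

# Reduced-depth refinement settings used by the end-to-end experiments (the
# annealing ladder and minimization are shortened to desk scale; all protocol
# logic is unchanged).
reduced_config <- function(selection = selection_config(), seed = 1, ...) {
  refinement_config(n_macrocycles = 4,
                    schedule = annealing_schedule(dt_temp = 200, timestep = 1),
                    min_steps = 60, selection = selection, seed = seed, ...)
}
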