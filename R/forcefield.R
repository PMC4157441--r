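#' Default element-pair bond detection cutoffs
#'
#' Distances (Angstrom) below which two atoms of the given elements, within one
#' residue or in consecutive residues of a chain, are considered bonded when
#' building a topology. Pairs not listed fall back to `default`.
#'
#' @return named numeric vector; names are sorted element pairs (`"C-N"`).
#' @export
default_bond_cutoffs <- function() {
  c("C-C" = 1.70, "C-N" = 1.70, "C-O" = 1.65, "C-S" = 1.95,
    "N-O" = 1.55, "S-S" = 2.20, default = 1.80)
}

pair_cutoff <- function(e1, e2, cutoffs) {
  key <- paste(pmin(e1, e2), pmax(e1, e2), sep = "-")
  out <- unname(cutoffs[key])
  out[is.na(out)] <- unname(cutoffs["default"])
  pmin(out, 2.0)  # no bond longer than 2.0 A at build time
}

#' Build a simplified stereochemical topology
#'
#' Infers covalent bonds by element-pair distance cutoffs within each residue
#' and between consecutive residues of the same chain (never across chains),
#' enumerates bond angles from the bond graph, and sets all equilibrium values
#' from the structure's own geometry. The resulting energy model is harmonic
#' bonds + harmonic angles + a purely repulsive quartic contact term for
#' non-excluded pairs (pairs separated by up to three bonds are excluded)
#' closer than `contact_factor` times the sum of their van der Waals radii.
#'
#' This is a deliberately reduced stereochemical term: uniform force constants,
#' no dihedrals, no electrostatics, no attractive nonbonded component.
#'
#' @param structure a [den_structure()] with near-ideal covalent geometry.
#' @param bond_cutoffs named cutoff vector, see [default_bond_cutoffs()].
#' @param k_bond bond force constant, kcal mol^-1 A^-2.
#' @param k_angle angle force constant, kcal mol^-1 rad^-2.
#' @param contact_factor fraction of the vdW-radius sum at which repulsion
#'   starts.
#' @param k_rep repulsion constant, kcal mol^-1 A^-4.
#' @return an object of class `den_topology`.
#' @export
build_topology <- function(structure, bond_cutoffs = default_bond_cutoffs(),
                           k_bond = 1000, k_angle = 100,
                           contact_factor = 0.9, k_rep = 50) {
  at <- structure$atoms
  xyz <- coords(structure)
  n <- nrow(at)
  bi <- integer(0); bj <- integer(0)
  for (ch in unique(at$chain)) {
    cidx <- which(at$chain == ch)
    resids <- sort(unique(at$residue_index[cidx]))
    for (r in resids) {
      a1 <- cidx[at$residue_index[cidx] %in% c(r, r + 1)]
      if (length(a1) < 2) next
      cand <- t(combn(a1, 2))
      # only intra-residue or consecutive-residue pairs
      keep <- abs(at$residue_index[cand[, 1]] - at$residue_index[cand[, 2]]) <= 1 &
        !(at$residue_index[cand[, 1]] == r + 1 & at$residue_index[cand[, 2]] == r + 1)
      cand <- cand[keep, , drop = FALSE]
      if (nrow(cand) == 0) next
      d <- sqrt(rowSums((xyz[cand[, 1], , drop = FALSE] -
                           xyz[cand[, 2], , drop = FALSE])^2))
      cut <- pair_cutoff(at$element[cand[, 1]], at$element[cand[, 2]], bond_cutoffs)
      sel <- d < cut
      bi <- c(bi, cand[sel, 1]); bj <- c(bj, cand[sel, 2])
    }
  }
  bonds <- unique(cbind(pmin(bi, bj), pmax(bi, bj)))
  if (nrow(bonds) == 0) stop("no bonds inferred; structure is not a bonded model")
  b0 <- sqrt(rowSums((xyz[bonds[, 1], , drop = FALSE] -
                        xyz[bonds[, 2], , drop = FALSE])^2))
  deg <- tabulate(c(bonds[, 1], bonds[, 2]), nbins = n)
  if (any(deg == 0))
    warning("topology: ", sum(deg == 0), " atom(s) with zero bonds")

  # adjacency list -> angles (all neighbor pairs at each vertex)
  nbr <- vector("list", n)
  for (p in seq_len(nrow(bonds))) {
    nbr[[bonds[p, 1]]] <- c(nbr[[bonds[p, 1]]], bonds[p, 2])
    nbr[[bonds[p, 2]]] <- c(nbr[[bonds[p, 2]]], bonds[p, 1])
  }
  ai <- integer(0); aj <- integer(0); ak <- integer(0)
  for (v in seq_len(n)) {
    nb <- nbr[[v]]
    if (length(nb) < 2) next
    pr <- t(combn(sort(nb), 2))
    ai <- c(ai, pr[, 1]); aj <- c(aj, rep(v, nrow(pr))); ak <- c(ak, pr[, 2])
  }
  angles <- cbind(ai, aj, ak)
  a0 <- numeric(nrow(angles))
  for (p in seq_len(nrow(angles))) {
    u <- xyz[angles[p, 1], ] - xyz[angles[p, 2], ]
    v <- xyz[angles[p, 3], ] - xyz[angles[p, 2], ]
    a0[p] <- acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
  }

  # nonbonded exclusions: pairs within three bonds (1-2, 1-3, 1-4)
  ex <- new.env(hash = TRUE, parent = emptyenv())
  add_pair <- function(i, j) {
    key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
    assign(key, TRUE, envir = ex)
  }
  for (v in seq_len(n)) {
    d1 <- nbr[[v]]
    d2 <- unique(unlist(nbr[d1]))
    d3 <- unique(unlist(nbr[d2]))
    for (u in unique(c(d1, d2, d3))) if (u != v) add_pair(v, u)
  }
  keys <- ls(ex)
  excl <- if (length(keys) > 0) {
    m <- do.call(rbind, strsplit(keys, "_", fixed = TRUE))
    cbind(as.integer(m[, 1]), as.integer(m[, 2]))
  } else matrix(integer(0), 0, 2)

  structure(list(
    bonds = bonds, b0 = b0, kb = rep(k_bond, nrow(bonds)),
    angles = angles, a0 = a0, ka = rep(k_angle, nrow(angles)),
    rcon = element_lookup(at$element, "vdw"), rfac = contact_factor,
    krep = k_rep, excl = excl, natoms = n
  ), class = "den_topology")
}

#' @export
print.den_topology <- function(x, ...) {
  cat(sprintf("den_topology: %d atoms, %d bonds, %d angles, %d exclusions\n",
              x$natoms, nrow(x$bonds), nrow(x$angles), nrow(x$excl)))
  invisible(x)
}

#' Stereochemical energy and forces
#'
#' @param xyz n x 3 coordinate matrix (Angstrom) or a [den_structure()].
#' @param topology a [build_topology()] result for the same atom set.
#' @return list with `energy` (kcal/mol) and `forces` (n x 3, kcal/mol/A).
#' @export
geom_energy_forces <- function(xyz, topology) {
  if (inherits(xyz, "den_structure")) xyz <- coords(xyz)
  stopifnot(nrow(xyz) == topology$natoms)
  cpp_geom_energy_forces(xyz, topology$bonds, topology$b0, topology$kb,
                         topology$angles, topology$a0, topology$ka,
                         topology$rcon, topology$rfac, topology$krep,
                         topology$excl)
}

# Gradient-based relaxation of the stereochemical term alone.
minimize_geometry <- function(xyz, topology, maxit = 300) {
  n <- nrow(xyz)
  fn <- function(p) cpp_geom_energy_forces(matrix(p, n, 3), topology$bonds,
    topology$b0, topology$kb, topology$angles, topology$a0, topology$ka,
    topology$rcon, topology$rfac, topology$krep, topology$excl)$energy
  gr <- function(p) -as.vector(cpp_geom_energy_forces(matrix(p, n, 3),
    topology$bonds, topology$b0, topology$kb, topology$angles, topology$a0,
    topology$ka, topology$rcon, topology$rfac, topology$krep, topology$excl)$forces)
  res <- optim(as.vector(xyz), fn, gr, method = "L-BFGS-B",
               control = list(maxit = maxit, factr = 1e4))
  matrix(res$par, n, 3)
}

# RMS bond-length deviation (A) + 0.1 * RMS angle deviation (degrees) from the
# topology equilibria: the geometry proxy used for model selection.
geometry_score <- function(xyz, topology) {
  if (inherits(xyz, "den_structure")) xyz <- coords(xyz)
  d <- sqrt(rowSums((xyz[topology$bonds[, 1], , drop = FALSE] -
                       xyz[topology$bonds[, 2], , drop = FALSE])^2))
  bond_rms <- sqrt(mean((d - topology$b0)^2))
  ang <- numeric(nrow(topology$angles))
  for (p in seq_len(nrow(topology$angles))) {
    u <- xyz[topology$angles[p, 1], ] - xyz[topology$angles[p, 2], ]
    v <- xyz[topology$angles[p, 3], ] - xyz[topology$angles[p, 2], ]
    ang[p] <- acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
  }
  angle_rms_deg <- sqrt(mean((ang - topology$a0)^2)) * 180 / pi
  bond_rms + 0.1 * angle_rms_deg
}
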