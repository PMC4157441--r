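#' Restraint-selection configuration
#'
#' Rules for picking random atom pairs as DEN restraints: a distance window
#' evaluated on the reference model (typically 3 to 15 Angstrom), a
#' primary-sequence separation window for same-chain pairs (typically at most
#' ten residues), and whether pairs across chains are allowed (off by default;
#' switching it on also lifts the sequence-separation test for those pairs, as
#' used for very-low-resolution multi-chain refinement).
#'
#' @param d_lo,d_hi distance window (Angstrom).
#' @param seq_sep_lo,seq_sep_hi residue-separation window (same-chain pairs).
#'   `seq_sep_hi = Inf` disables the upper limit.
#' @param allow_inter_chain logical; allow pairs with different chain ids.
#' @param n_restraints integer, or `"auto"` for one restraint per selected
#'   atom.
#' @param atom_subset `NULL` (all non-hydrogen atoms), a logical/integer index
#'   vector, or a predicate `function(atoms_df)` returning a logical vector.
#'   Restricting the subset supports partial/incomplete reference models.
#' @return an object of class `den_selection_config`.
#' @export
selection_config <- function(d_lo = 3.0, d_hi = 15.0,
                             seq_sep_lo = 0, seq_sep_hi = 10,
                             allow_inter_chain = FALSE,
                             n_restraints = "auto",
                             atom_subset = NULL) {
  if (!(d_lo > 0 && d_lo < d_hi)) stop("need 0 < d_lo < d_hi")
  if (!(seq_sep_lo >= 0 && seq_sep_lo <= seq_sep_hi))
    stop("need 0 <= seq_sep_lo <= seq_sep_hi")
  if (!identical(n_restraints, "auto")) {
    n_restraints <- as.integer(n_restraints)
    if (n_restraints < 1) stop("n_restraints must be >= 1 or \"auto\"")
  }
  structure(list(d_lo = d_lo, d_hi = d_hi, seq_sep_lo = seq_sep_lo,
                 seq_sep_hi = seq_sep_hi,
                 allow_inter_chain = isTRUE(allow_inter_chain),
                 n_restraints = n_restraints, atom_subset = atom_subset),
            class = "den_selection_config")
}

resolve_atom_subset <- function(structure, atom_subset) {
  at <- structure$atoms
  if (is.null(atom_subset)) return(which(toupper(at$element) != "H"))
  if (is.function(atom_subset)) return(which(atom_subset(at)))
  if (is.logical(atom_subset)) return(which(atom_subset))
  as.integer(atom_subset)
}

check_correspondence <- function(a, b) {
  if (n_atoms(a) != n_atoms(b))
    stop("atom correspondence error: structures have ",
         n_atoms(a), " vs ", n_atoms(b), " atoms")
  if (!identical(a$atoms$name, b$atoms$name) ||
      !identical(a$atoms$chain, b$atoms$chain))
    stop("atom correspondence error: atom names/chains differ or are reordered")
  invisible(TRUE)
}

#' Select DEN restraint pairs
#'
#' Draws a uniform random sample (without replacement, via a seeded shuffle)
#' from the set of atom pairs eligible under `config`. Eligibility (the
#' distance window and chain/sequence-separation rules) is evaluated on the
#' reference model. Current equilibrium distances `d0` are initialized from
#' the starting structure, so the starting model sits at the minimum of the
#' DEN potential and feels no initial restraint force; `d_ref` records the
#' reference-model distances used by the deformation update. The pair list
#' stays fixed for the whole refinement; repeats re-select with new seeds.
#'
#' @param structure starting model (a [den_structure()]); source of `d0`.
#' @param reference reference model with identical atoms in identical order;
#'   source of eligibility and `d_ref`.
#' @param config a [selection_config()].
#' @param seed integer selection seed.
#' @return an object of class `den_network` with elements `restraints`
#'   (data.frame `i, j, d0, d_ref`), `selection_seed`, `config`.
#' @export
select_restraints <- function(structure, reference, config = selection_config(),
                              seed = 1) {
  check_correspondence(structure, reference)
  sub <- resolve_atom_subset(reference, config$atom_subset)
  if (length(sub) < 2) stop("restraint selection error: fewer than 2 atoms in subset")
  at <- reference$atoms
  xyz_ref <- coords(reference)[sub, , drop = FALSE]
  dmat <- as.matrix(stats::dist(xyz_ref))
  pair_idx <- which(upper.tri(dmat), arr.ind = TRUE)
  d <- dmat[pair_idx]
  gi <- sub[pair_idx[, 1]]
  gj <- sub[pair_idx[, 2]]
  in_window <- d >= config$d_lo & d <= config$d_hi
  same_chain <- at$chain[gi] == at$chain[gj]
  sep <- abs(at$residue_index[gi] - at$residue_index[gj])
  ok_same <- same_chain & sep >= config$seq_sep_lo & sep <= config$seq_sep_hi
  ok_cross <- !same_chain & config$allow_inter_chain
  eligible <- which(in_window & (ok_same | ok_cross))
  if (length(eligible) == 0)
    stop("restraint selection error: no eligible atom pairs under the configuration")
  n_want <- if (identical(config$n_restraints, "auto")) length(sub) else config$n_restraints
  take <- min(n_want, length(eligible))
  picked <- eligible[with_seed(seed, sample.int(length(eligible)))][seq_len(take)]
  i <- gi[picked]; j <- gj[picked]
  xyz_start <- coords(structure)
  d0 <- sqrt(rowSums((xyz_start[i, , drop = FALSE] - xyz_start[j, , drop = FALSE])^2))
  structure(list(
    restraints = data.frame(i = i, j = j, d0 = d0, d_ref = d[picked]),
    selection_seed = as.integer(seed), config = config
  ), class = "den_network")
}

#' @export
print.den_network <- function(x, ...) {
  cat(sprintf("den_network: %d restraints (seed %d)\n",
              nrow(x$restraints), x$selection_seed))
  cat(sprintf("  d0 range %.2f-%.2f A, d_ref range %.2f-%.2f A\n",
              min(x$restraints$d0), max(x$restraints$d0),
              min(x$restraints$d_ref), max(x$restraints$d_ref)))
  invisible(x)
}

#' DEN elastic-network energy and forces
#'
#' \eqn{E_{DEN} = w_{DEN} \sum_{ij} (d_{ij} - d^0_{ij})^2} over the restrained
#' pairs, with the per-restraint spring constant absorbed into the single
#' weight `w_den`. Forces are the exact negative gradient; atoms in no
#' restraint feel zero force.
#'
#' @param xyz n x 3 coordinate matrix or a [den_structure()].
#' @param network a [select_restraints()] result.
#' @param w_den restraint weight (>= 0).
#' @return list with `energy` and `forces` (n x 3).
#' @export
den_energy_forces <- function(xyz, network, w_den) {
  if (inherits(xyz, "den_structure")) xyz <- coords(xyz)
  r <- network$restraints
  cpp_den_energy_forces(r$i, r$j, r$d0, xyz, w_den)
}

#' Deform the DEN equilibrium distances
#'
#' The update applied at each temperature-decrement step of slow cooling:
#' \deqn{d^0_{ij} \leftarrow d^0_{ij} + \kappa [\gamma (d_{ij} - d^0_{ij})
#'   + (1-\gamma)(d^{ref}_{ij} - d^0_{ij})]}
#' where \eqn{d_{ij}} is the current model distance. At `gamma = 0` the
#' equilibria relax geometrically towards the reference distances; at
#' `gamma = 1` they track the refining model and the reference distances are
#' never used.
#'
#' @param network a `den_network`.
#' @param xyz current n x 3 coordinates or a [den_structure()].
#' @param gamma deformation parameter in `[0, 1]`.
#' @param kappa update rate in `(0, 1]`.
#' @return the network with updated `d0`; all other fields unchanged.
#' @export
update_equilibrium <- function(network, xyz, gamma, kappa = 0.1) {
  if (!(is.numeric(gamma) && gamma >= 0 && gamma <= 1))
    stop("parameter error: gamma must be in [0, 1]")
  if (!(is.numeric(kappa) && kappa > 0 && kappa <= 1))
    stop("parameter error: kappa must be in (0, 1]")
  if (inherits(xyz, "den_structure")) xyz <- coords(xyz)
  r <- network$restraints
  d <- cpp_pair_distances(r$i, r$j, xyz)
  network$restraints$d0 <- r$d0 +
    kappa * (gamma * (d - r$d0) + (1 - gamma) * (r$d_ref - r$d0))
  network
}

#' Serialize a restraint list
#'
#' Writes the network as a TSV with columns
#' `chain_i resi_i atom_i chain_j resi_j atom_j d0 d_ref` for inspection and
#' replay; [read_restraints()] rebuilds the network against a structure with
#' the same atom naming.
#'
#' @param network a `den_network`.
#' @param structure the structure the indices refer to.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_restraints <- function(network, structure, path) {
  at <- structure$atoms
  r <- network$restraints
  df <- data.frame(
    chain_i = at$chain[r$i], resi_i = at$residue_index[r$i], atom_i = at$name[r$i],
    chain_j = at$chain[r$j], resi_j = at$residue_index[r$j], atom_j = at$name[r$j],
    d0 = r$d0, d_ref = r$d_ref
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_restraints
#' @export
read_restraints <- function(path, structure) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  at <- structure$atoms
  key <- paste(at$chain, at$residue_index, at$name)
  i <- match(paste(df$chain_i, df$resi_i, df$atom_i), key)
  j <- match(paste(df$chain_j, df$resi_j, df$atom_j), key)
  if (anyNA(i) || anyNA(j))
    stop("restraint file refers to atoms absent from the structure")
  structure(list(restraints = data.frame(i = i, j = j, d0 = df$d0, d_ref = df$d_ref),
                 selection_seed = NA_integer_, config = NULL),
            class = "den_network")
}
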