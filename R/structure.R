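#' Coordinate model container
#'
#' A `den_structure` holds an ordered atom table and a P1 unit cell. The atom
#' table has one row per atom with columns `serial`, `name` (atom name),
#' `element`, `resno` (author residue number, preserved for output),
#' `residue_index` (0-based sequential position within its chain, gap-free),
#' `resname`, `chain`, `x`, `y`, `z` (Angstrom), `occ` and `b` (Angstrom^2).
#'
#' @param atoms data.frame as described above.
#' @param cell numeric length-6 vector `(a, b, c, alpha, beta, gamma)`,
#'   lengths in Angstrom, angles in degrees.
#' @return an object of class `den_structure`.
#' @export
den_structure <- function(atoms, cell) {
  required <- c("serial", "name", "element", "resno", "residue_index",
                "resname", "chain", "x", "y", "z", "occ", "b")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0)
    stop("atom table is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0) stop("empty structure (no atoms)")
  if (any(atoms$b < 0)) stop("negative B factor")
  if (any(atoms$occ < 0 | atoms$occ > 1)) stop("occupancy outside [0, 1]")
  cell <- as.numeric(cell)
  if (length(cell) != 6 || any(cell[1:3] <= 0))
    stop("unit cell must be 6 numbers with positive lengths")
  element_lookup(atoms$element, "mass")  # validates symbols
  for (ch in unique(atoms$chain)) {
    ri <- atoms$residue_index[atoms$chain == ch]
    if (is.unsorted(ri)) stop("residue_index not non-decreasing in chain ", ch)
  }
  structure(list(atoms = atoms, cell = cell), class = "den_structure")
}

#' @export
print.den_structure <- function(x, ...) {
  cat(sprintf("den_structure: %d atoms, %d chain(s), %d residue(s)\n",
              nrow(x$atoms), length(unique(x$atoms$chain)), n_residues(x)))
  cat(sprintf("  cell: %.2f %.2f %.2f A  %.1f %.1f %.1f deg\n",
              x$cell[1], x$cell[2], x$cell[3], x$cell[4], x$cell[5], x$cell[6]))
  invisible(x)
}

#' Coordinate access
#'
#' @param structure a [den_structure()].
#' @return `coords` returns the n x 3 coordinate matrix (Angstrom).
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' @rdname coords
#' @param value n x 3 numeric matrix of replacement coordinates.
#' @export
`coords<-` <- function(structure, value) {
  stopifnot(is.matrix(value), nrow(value) == nrow(structure$atoms), ncol(value) == 3)
  structure$atoms$x <- value[, 1]
  structure$atoms$y <- value[, 2]
  structure$atoms$z <- value[, 3]
  structure
}

#' @rdname coords
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' @rdname coords
#' @export
n_residues <- function(structure) {
  sum(vapply(split(structure$atoms$residue_index, structure$atoms$chain),
             function(ri) length(unique(ri)), integer(1)))
}

#' Chain to residue grouping
#'
#' @param structure a [den_structure()].
#' @return named list (one entry per chain) of per-chain atom index vectors.
#' @export
chain_indices <- function(structure) {
  split(seq_len(n_atoms(structure)), structure$atoms$chain)
}

# 0-based sequential residue index per chain from raw author numbering.
sequential_residue_index <- function(chain, resno) {
  out <- integer(length(chain))
  for (ch in unique(chain)) {
    sel <- chain == ch
    r <- resno[sel]
    out[sel] <- cumsum(c(0L, as.integer(diff(r) != 0)))
  }
  out
}

# Orthogonalization matrix (fractional -> Cartesian), PDB convention:
# a along x, b in the xy plane.
orthogonalization_matrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(
    a, b * cos(ga), cc * cos(be),
    0, b * sin(ga), cc * (cos(al) - cos(be) * cos(ga)) / sin(ga),
    0, 0, cc * v / sin(ga)
  ), nrow = 3, byrow = TRUE)
}

# Fractionalization matrix (Cartesian -> fractional).
fractionalization_matrix <- function(cell) solve(orthogonalization_matrix(cell))

#' Read a PDB-format coordinate file
#'
#' Interprets ATOM/HETATM/CRYST1/TER/END records of the fixed-column v3.3
#' subset; all other record types are ignored. Record-level parsing is done by
#' \pkg{bio3d}; the CRYST1 unit cell is read here because \pkg{bio3d} discards
#' it. When no CRYST1 record is present, a padded P1 box (10 Angstrom margin)
#' is synthesized around the model.
#'
#' Not supported: mmCIF, altloc identifiers, ANISOU records, insertion codes.
#'
#' @param path file path.
#' @return a [den_structure()].
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  n_atom_rec <- sum(rec %in% c("ATOM  ", "HETATM"))
  if (n_atom_rec == 0) stop("PDB format error: file contains no ATOM/HETATM records")
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("PDB format error: ", conditionMessage(e)))
  at <- pdb$atom
  bad <- which(is.na(at$x) | is.na(at$y) | is.na(at$z))
  if (length(bad) > 0) {
    ln <- which(rec %in% c("ATOM  ", "HETATM"))[bad[1]]
    stop("PDB format error: unparsable coordinate field at line ", ln)
  }
  elem <- toupper(trimws(at$elesy))
  blank <- is.na(elem) | elem == ""
  if (any(blank)) {
    # fall back to the first letter of the atom name
    elem[blank] <- substr(gsub("[^A-Za-z].*", "", trimws(at$elety[blank])), 1, 1)
  }
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "A"
  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    element = elem,
    resno = at$resno,
    residue_index = sequential_residue_index(chain, at$resno),
    resname = trimws(at$resid),
    chain = chain,
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    stringsAsFactors = FALSE
  )
  cry <- lines[rec == "CRYST1"]
  if (length(cry) >= 1) {
    f <- suppressWarnings(as.numeric(c(
      substr(cry[1], 7, 15), substr(cry[1], 16, 24), substr(cry[1], 25, 33),
      substr(cry[1], 34, 40), substr(cry[1], 41, 47), substr(cry[1], 48, 54)
    )))
    if (anyNA(f)) stop("PDB format error: unparsable CRYST1 record")
    cell <- f
  } else {
    cell <- default_cell(as.matrix(atoms[, c("x", "y", "z")]))
  }
  den_structure(atoms, cell)
}

# Padded orthorhombic P1 box around a coordinate set.
default_cell <- function(xyz, margin = 10) {
  ext <- apply(xyz, 2, function(u) diff(range(u)))
  c(ext + 2 * margin, 90, 90, 90)
}

#' Write a PDB-format coordinate file
#'
#' Writes CRYST1 (space group "P 1") followed by fixed-column ATOM records,
#' per-chain TER records and END. Inverse of [read_pdb()] up to format
#' precision (1e-3 Angstrom in coordinates, 1e-2 in B factors).
#'
#' @param structure a [den_structure()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "den_structure"))
  at <- structure$atoms
  if (nrow(at) == 0) stop("refusing to write an empty structure")
  xyz <- coords(structure)
  if (any(xyz >= 10000 | xyz <= -1000))
    stop("PDB format error: coordinate magnitude exceeds fixed field width")
  cl <- structure$cell
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   cl[1], cl[2], cl[3], cl[4], cl[5], cl[6])
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  bio3d::write.pdb(file = tmp, xyz = as.numeric(t(xyz)),
                   eleno = at$serial, elety = at$name, resid = at$resname,
                   chain = at$chain, resno = at$resno,
                   o = at$occ, b = at$b, elesy = at$element)
  body <- readLines(tmp, warn = FALSE)
  body <- body[substr(body, 1, 3) != "END"]
  # insert TER records at chain boundaries
  atom_lines <- which(substr(body, 1, 6) %in% c("ATOM  ", "HETATM"))
  breaks <- which(diff(match(at$chain, unique(at$chain))) != 0)
  out <- character(0)
  prev <- 0
  for (brk in c(breaks, nrow(at))) {
    out <- c(out, body[atom_lines[(prev + 1):brk]], "TER")
    prev <- brk
  }
  writeLines(c(cryst, out, "END"), path)
  invisible(path)
}
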