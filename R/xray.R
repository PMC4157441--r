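#' Reflection set container
#'
#' Holds Friedel-unique P1 Miller indices with optional observed amplitudes,
#' uncertainties and cross-validation (test-set) flags.
#'
#' @param cell unit cell, length-6 numeric.
#' @param hkl n x 3 integer matrix of Miller indices.
#' @param d_min resolution limit (Angstrom).
#' @param f_obs optional non-negative amplitudes.
#' @param sigma optional per-reflection uncertainties.
#' @param is_test optional logical test-set flags.
#' @return an object of class `den_reflections` with an `s` column (1/d).
#' @export
reflection_set <- function(cell, hkl, d_min, f_obs = NULL, sigma = NULL,
                           is_test = NULL) {
  hkl <- matrix(as.numeric(hkl), ncol = 3)
  if (any(rowSums(abs(hkl)) == 0)) stop("(0,0,0) is not a valid reflection")
  Mfrac <- fractionalization_matrix(cell)
  svec <- hkl %*% Mfrac        # rows: reciprocal vectors in Cartesian A^-1
  s <- sqrt(rowSums(svec^2))   # 1/d
  if (any(s > 1 / d_min + 1e-9)) stop("reflection beyond the stated d_min")
  if (!is.null(f_obs)) {
    stopifnot(length(f_obs) == nrow(hkl))
    if (any(f_obs < 0)) stop("negative observed amplitude")
  }
  structure(list(cell = as.numeric(cell), hkl = hkl, s = s, d_min = d_min,
                 f_obs = f_obs, sigma = sigma, is_test = is_test),
            class = "den_reflections")
}

#' @export
print.den_reflections <- function(x, ...) {
  nt <- if (is.null(x$is_test)) NA_integer_ else sum(x$is_test)
  cat(sprintf("den_reflections: %d reflections to %.2f A (N_test = %s)\n",
              nrow(x$hkl), x$d_min,
              if (is.na(nt)) "unset" else nt))
  invisible(x)
}

#' Generate Friedel-unique P1 reflection indices
#'
#' Enumerates all Miller indices with resolution `d >= d_min`, excluding
#' (0,0,0), and keeps one member of each Friedel pair by the hemisphere rule:
#' the first nonzero component of `(h, k, l)` must be positive.
#'
#' @param cell unit cell, length-6 numeric.
#' @param d_min resolution limit (Angstrom).
#' @return a [reflection_set()] without amplitudes.
#' @export
generate_hkl <- function(cell, d_min) {
  stopifnot(d_min > 0)
  O <- orthogonalization_matrix(cell)
  # generous index bounds from the direct cell lengths
  hmax <- pmax(1L, as.integer(ceiling(cell[1:3] / d_min)) + 1L)
  grid <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                                l = -hmax[3]:hmax[3]))
  Mfrac <- solve(O)
  s <- sqrt(rowSums((grid %*% Mfrac)^2))
  keep <- s <= 1 / d_min & s > 0
  hemi <- grid[, 1] > 0 |
    (grid[, 1] == 0 & grid[, 2] > 0) |
    (grid[, 1] == 0 & grid[, 2] == 0 & grid[, 3] > 0)
  sel <- keep & hemi
  if (!any(sel)) stop("empty reflection set: d_min exceeds all cell dimensions")
  reflection_set(cell, grid[sel, , drop = FALSE], d_min)
}

# Per-atom, per-reflection scattering weights occ * f_elem(s) * exp(-B s^2/4).
scattering_weights <- function(structure, refl) {
  at <- structure$atoms
  f <- form_factors(at$element, refl$s)
  at$occ * f * exp(-outer(at$b, refl$s^2) / 4)
}

#' Calculated structure factors
#'
#' Direct summation over atoms in P1:
#' \deqn{F(h) = \sum_i occ_i f_i(s) e^{-B_i s^2/4} e^{2\pi i\, h\cdot x_i}}
#' with fractional coordinates \eqn{x_i} and \eqn{s = 1/d}.
#'
#' @param structure a [den_structure()].
#' @param refl a [reflection_set()] with a cell consistent with the structure.
#' @return complex vector, one entry per reflection.
#' @export
calc_structure_factors <- function(structure, refl) {
  if (max(abs(structure$cell - refl$cell)) > 1e-6)
    stop("unit cell mismatch between structure and reflections")
  Mfrac <- fractionalization_matrix(structure$cell)
  xfrac <- coords(structure) %*% t(Mfrac)
  cpp_structure_factors(refl$hkl, xfrac, scattering_weights(structure, refl))
}

#' Least-squares amplitude target and forces
#'
#' \eqn{E = w_{Xray} \sum_{work} (F_{obs} - k |F_{calc}|)^2} with the overall
#' scale `k` fitted in closed form over the work reflections. Test (free-set)
#' reflections never contribute to the energy or the forces when
#' `use_work_only` is `TRUE` (the default); setting it `FALSE` treats every
#' reflection as part of the target, for data without cross-validation flags.
#'
#' @param structure a [den_structure()].
#' @param refl a [reflection_set()] with `f_obs`.
#' @param w_xray target weight.
#' @param use_work_only logical, see above.
#' @return list with `energy`, `forces` (n x 3), `scale`, `f_calc`.
#' @export
xray_energy_forces <- function(structure, refl, w_xray = 1, use_work_only = TRUE) {
  if (is.null(refl$f_obs)) stop("reflections carry no observed amplitudes")
  if (all(refl$f_obs == 0)) stop("scaling error: all observed amplitudes are zero")
  target <- if (use_work_only) {
    if (is.null(refl$is_test)) rep(TRUE, nrow(refl$hkl)) else !refl$is_test
  } else rep(TRUE, nrow(refl$hkl))
  Mfrac <- fractionalization_matrix(structure$cell)
  xfrac <- coords(structure) %*% t(Mfrac)
  Gcart <- 2 * pi * refl$hkl %*% Mfrac
  cpp_xray_energy_forces(refl$hkl, Gcart, xfrac,
                         scattering_weights(structure, refl),
                         refl$f_obs, target, w_xray)
}

#' Crystallographic R factors
#'
#' \eqn{R = \sum |F_{obs} - k |F_{calc}|| / \sum F_{obs}} computed separately
#' over the work and test subsets, with the scale `k` fitted (least squares)
#' on the work reflections only.
#'
#' @param refl a [reflection_set()] with `f_obs` and `is_test` flags.
#' @param f_calc complex or numeric calculated amplitudes.
#' @return list with `r_work` and `r_free`.
#' @export
r_factors <- function(refl, f_calc) {
  if (is.null(refl$f_obs)) stop("reflections carry no observed amplitudes")
  if (is.null(refl$is_test) || !any(refl$is_test))
    stop("undefined R_free: empty test set")
  if (!any(!refl$is_test)) stop("empty work set")
  fc <- Mod(f_calc)
  work <- !refl$is_test
  k <- sum(refl$f_obs[work] * fc[work]) / sum(fc[work]^2)
  rfac <- function(sel)
    sum(abs(refl$f_obs[sel] - k * fc[sel])) / sum(refl$f_obs[sel])
  list(r_work = rfac(work), r_free = rfac(refl$is_test))
}

#' Assign cross-validation (test-set) flags
#'
#' Flags each reflection as test with the given probability, deterministically
#' by seed; guarantees at least one test reflection.
#'
#' @param refl a [reflection_set()].
#' @param fraction test fraction, in `(0, 0.5)`.
#' @param seed integer seed.
#' @return the reflection set with `is_test` filled in.
#' @export
assign_test_set <- function(refl, fraction = 0.10, seed = 1) {
  if (!(fraction > 0 && fraction < 0.5))
    stop("parameter error: test fraction must be in (0, 0.5)")
  n <- nrow(refl$hkl)
  flags <- with_seed(seed, {
    fl <- runif(n) < fraction
    if (!any(fl)) fl[sample.int(n, 1)] <- TRUE
    fl
  })
  refl$is_test <- flags
  refl
}

#' Reflection file I/O
#'
#' Whitespace-separated columns `H K L FOBS SIGMA FREE` with a `#`-comment
#' header carrying the cell, the resolution limit and the Friedel hemisphere
#' rule. Amplitudes are written with enough digits for an exact round trip.
#'
#' @param refl a [reflection_set()] with `f_obs`.
#' @param path file path.
#' @return `read_reflections` returns a [reflection_set()];
#'   `write_reflections` returns `path` invisibly.
#' @export
write_reflections <- function(refl, path) {
  if (is.null(refl$f_obs)) stop("reflections carry no observed amplitudes")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# denrefine reflection file",
    sprintf("# cell %.17g %.17g %.17g %.17g %.17g %.17g",
            refl$cell[1], refl$cell[2], refl$cell[3],
            refl$cell[4], refl$cell[5], refl$cell[6]),
    sprintf("# d_min %.17g", refl$d_min),
    "# hemisphere: first nonzero of (h,k,l) positive",
    "# columns: H K L FOBS SIGMA FREE"
  ), con)
  sig <- refl$sigma %||% rep(0, nrow(refl$hkl))
  fre <- as.integer(refl$is_test %||% rep(FALSE, nrow(refl$hkl)))
  writeLines(sprintf("%d %d %d %.17g %.17g %d",
                     refl$hkl[, 1], refl$hkl[, 2], refl$hkl[, 3],
                     refl$f_obs, sig, fre), con)
  invisible(path)
}

#' @rdname write_reflections
#' @export
read_reflections <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  cell_line <- hdr[grepl("^# cell ", hdr)]
  dmin_line <- hdr[grepl("^# d_min ", hdr)]
  if (length(cell_line) == 0 || length(dmin_line) == 0)
    stop("reflection file header lacks cell or d_min")
  cell <- as.numeric(strsplit(trimws(sub("^# cell ", "", cell_line[1])), "\\s+")[[1]])
  d_min <- as.numeric(sub("^# d_min ", "", dmin_line[1]))
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  m <- read.table(text = body, col.names = c("H", "K", "L", "FOBS", "SIGMA", "FREE"))
  reflection_set(cell, as.matrix(m[, 1:3]), d_min, f_obs = m$FOBS,
                 sigma = m$SIGMA, is_test = m$FREE != 0)
}
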