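#' Compare a model with a known structure
#'
#' Atom-wise comparison in the crystal frame by default (no superposition,
#' the convention under which refinement-frame RMSD values are meaningful);
#' optionally after least-squares superposition by the quaternion method.
#' Reports all-atom and C-alpha RMSD, the fraction of atoms deviating by less
#' than 2 Angstrom, and the geometry score of the model evaluated against a
#' topology built from the comparison structure.
#'
#' @param model refined model.
#' @param truth comparison structure with identical atoms in identical order.
#' @param superpose logical; superpose `model` onto `truth` first.
#' @return an object of class `den_comparison` with fields `rmsd_all`,
#'   `rmsd_ca`, `fraction_within_2A`, `geometry_score`, `superposed`,
#'   `deviations` (per-atom).
#' @export
compare_structures <- function(model, truth, superpose = FALSE) {
  check_correspondence(model, truth)
  xm <- coords(model)
  xt <- coords(truth)
  if (superpose) xm <- superpose_xyz(xm, xt)
  dev <- sqrt(rowSums((xm - xt)^2))
  ca <- model$atoms$name == "CA"
  topo <- build_topology(truth)
  structure(list(
    rmsd_all = sqrt(mean(dev^2)),
    rmsd_ca = if (any(ca)) sqrt(mean(dev[ca]^2)) else NA_real_,
    fraction_within_2A = mean(dev < 2),
    geometry_score = geometry_score(coords(model), topo),
    superposed = isTRUE(superpose),
    deviations = dev
  ), class = "den_comparison")
}

#' @export
print.den_comparison <- function(x, ...) {
  cat(sprintf(
    "den_comparison: RMSD %.3f A (CA %.3f), %.0f%% of atoms within 2 A%s\n",
    x$rmsd_all, x$rmsd_ca, 100 * x$fraction_within_2A,
    if (x$superposed) " [superposed]" else ""))
  invisible(x)
}

#' @rdname compare_structures
#' @param path output JSON path.
#' @return `write_comparison_json` returns `path` invisibly.
#' @export
write_comparison_json <- function(model, truth, path, superpose = FALSE) {
  cmp <- compare_structures(model, truth, superpose)
  jsonlite::write_json(cmp[c("rmsd_all", "rmsd_ca", "fraction_within_2A",
                             "geometry_score", "superposed")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
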