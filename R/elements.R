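# Per-element constants: atomic mass (amu), van der Waals radius (A) used by
# the repulsive contact term, and a one-Gaussian-plus-constant scattering
# factor f(s) = a * exp(-b * s^2 / 4) + c with s = 1/d (so s^2/4 equals
# (sin(theta)/lambda)^2). The coefficients are coarse single-Gaussian fits to
# tabulated curves with f(0) = Z; synthetic observed and calculated amplitudes
# always use the same table, so refinement behaviour does not depend on the
# fit quality. Overridable via options(denrefine.elements = <data.frame>).
.element_table <- data.frame(
  element = c("H", "C", "N", "O", "S", "P", "FE", "MG", "ZN"),
  mass    = c(1.008, 12.011, 14.007, 15.999, 32.06, 30.974, 55.845, 24.305, 65.38),
  vdw     = c(1.10, 1.70, 1.55, 1.52, 1.80, 1.80, 1.40, 1.73, 1.39),
  ff_a    = c(0.9, 4.6, 5.3, 6.0, 10.8, 10.0, 18.0, 8.0, 20.0),
  ff_b    = c(30.0, 22.0, 18.0, 15.0, 12.0, 13.0, 8.0, 10.0, 8.0),
  ff_c    = c(0.1, 1.4, 1.7, 2.0, 5.2, 5.0, 8.0, 4.0, 10.0),
  stringsAsFactors = FALSE
)

element_table <- function() {
  tab <- getOption("denrefine.elements", .element_table)
  tab
}

element_lookup <- function(elements, column) {
  tab <- element_table()
  idx <- match(toupper(elements), tab$element)
  if (anyNA(idx)) {
    bad <- unique(elements[is.na(idx)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         " (no tabulated mass/scattering coefficients)")
  }
  tab[[column]][idx]
}

#' Atomic scattering factors
#'
#' Evaluates the per-element form factor \eqn{f(s) = a e^{-b s^2/4} + c}
#' at scattering vector magnitudes \eqn{s = 1/d} (inverse Angstrom).
#'
#' @param elements character vector of element symbols.
#' @param s numeric vector of 1/d values (inverse Angstrom).
#' @return matrix of dimension `length(elements) x length(s)`.
#' @export
form_factors <- function(elements, s) {
  a <- element_lookup(elements, "ff_a")
  b <- element_lookup(elements, "ff_b")
  cc <- element_lookup(elements, "ff_c")
  s2 <- s^2
  a * exp(-outer(b, s2) / 4) + cc
}
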