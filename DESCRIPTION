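Package: denrefine
Title: Deformable Elastic Network Refinement for Low-Resolution
    Crystallographic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Refinement of macromolecular models against low-resolution
    diffraction amplitudes guided by deformable elastic network (DEN)
    restraints: sparse harmonic distance restraints whose equilibrium
    values deform slowly during simulated-annealing refinement, pulled
    partly towards the refining model and partly towards a reference
    model. Includes slow-cooling Cartesian molecular dynamics with a
    least-squares amplitude target, segmented rigid-body and grouped
    B-factor refinement, the (gamma, w_DEN) parameter grid search with
    R-free based model selection, and a synthetic-data module that
    builds toy helical structures, perturbed starting models and
    synthetic reflection data for end-to-end experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
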