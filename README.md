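# denrefine

Deformable elastic network (DEN) refinement of macromolecular models against
low-resolution diffraction amplitudes, in R.

At resolutions worse than ~3.5 Å the number of observed amplitudes is
comparable to the number of coordinate degrees of freedom, and unrestrained
refinement tends to degrade a model instead of improving it. DEN refinement
counters this with a sparse set of harmonic distance restraints drawn at
random between atom pairs of a *reference model* (3–15 Å apart, within ten
residues in sequence by default),

    E_DEN = w_DEN * sum_ij ( d_ij - d0_ij )^2 ,

whose equilibrium values `d0_ij` *deform* at every temperature decrement of a
slow-cooling simulated-annealing refinement:

    d0_ij <- d0_ij + kappa * [ gamma * (d_ij - d0_ij) + (1 - gamma) * (d_ref_ij - d0_ij) ] .

The deformation parameter `gamma` in [0, 1] sets how much the restraints may
leave the reference model (`gamma = 0`: pinned to the reference; `gamma = 1`:
the network tracks the refining model and the reference is never consulted),
and `kappa` (default 0.1) sets the deformation speed. `(gamma, w_DEN)` are
chosen by a grid search (gamma spacing 0.2; w_DEN in 3, 10, 30, 100, 300;
5–20 repeats per cell with fresh restraint selections and velocities) that
minimizes R_free; R_free differences smaller than `2/sqrt(N_test)` are
treated as insignificant and broken by stereochemical quality.

The package provides the full protocol — restraint selection, the composite
target `E_MM + w_Xray * E_Xray + E_DEN` with analytic forces, slow cooling
(3000 K to 0 K in 50 K decrements, six steps per level), segmented
rigid-body pre-refinement, grouped B-factor refinement, macrocycles with a
`gamma = 0` first cycle and restraint-free final cycles, grid search and
model selection — plus a synthetic-data module (ideal poly-alanine helices
and bundles, calibrated perturbations, synthetic amplitudes with
cross-validation flags) so everything runs end-to-end with no external data.

## Worked example

```r
library(denrefine)

# a 20-residue toy problem: truth, a start 2.5 A away, amplitudes to 3.5 A
sc <- make_benchmark_scenario("lowres_helix", seed = 42)
print(sc)
#> den_scenario 'lowres_helix': 100 atoms, 3279 reflections to 3.5 A, start RMSD 2.46 A

cfg <- refinement_config(gamma = 0, w_den = 100, n_macrocycles = 4,
                         schedule = annealing_schedule(dt_temp = 200, timestep = 1),
                         min_steps = 60, seed = 7)
res <- run_den_refinement(sc$start, sc$reference, sc$refl, cfg)
print(res)
#> den_refinement: R_work 0.0532  R_free 0.0575  geometry 0.220  drift 0.275 A

compare_structures(res$model, sc$truth)
#> den_comparison: RMSD 1.991 A (CA 1.964), 63% of atoms within 2 A
```

The refinement lowered the model error from 2.46 Å to 2.0 Å against data the
truth model fits at R ≈ 0.04 (the 5% synthetic amplitude noise floor); the
`drift` value is the coordinate movement over the final two restraint-free
macrocycles, the protocol's convergence probe. A parameter search
(`run_grid()` + `select_best()`) instead of a single `(gamma, w_den)` pair
is the recommended way to run real problems; `export_contours()` writes the
per-cell R_free summary for contour plots.

A command-line front end wrapping these functions is installed at
`inst/cli/den.R` (subcommands `make-fixture`, `refine`, `gridsearch`,
`validate`).

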