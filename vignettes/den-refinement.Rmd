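---
title: "Deformable elastic network refinement: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deformable elastic network refinement: model, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Crystallographic refinement at low resolution (worse than about 3.5 Å) is
under-determined: the number of observed amplitudes is comparable to, or
smaller than, the number of coordinate degrees of freedom. Unrestrained
refinement in this regime tends to degrade a starting model rather than
improve it, because the data cannot by themselves distinguish physically
reasonable rearrangements from noise fitting. Deformable elastic network
(DEN) refinement addresses this by adding a sparse set of harmonic distance
restraints whose *equilibrium values slowly deform* during refinement: the
restraints preserve the local structure of a reference model wherever the
data are silent, while letting exactly those distances change for which the
diffraction data supply real information.

`denrefine` implements the complete method — restraint selection, the
deformation update, slow-cooling simulated-annealing refinement against an
amplitude target, segmented rigid-body and grouped B-factor refinement, and
the two-dimensional (γ, w~DEN~) parameter search with R~free~-based model
selection — together with a synthetic-data module so that every claim can be
exercised end-to-end on data generated in code.

## The model

A number *N* of atom pairs (i, j) is drawn at random from the pairs that are,
in the **reference model**, separated by 3–15 Å in space and by at most ten
residues in sequence (both windows configurable; inter-chain pairs are
excluded by default). The elastic network potential is

$$E_{\mathrm{DEN}} = w_{\mathrm{DEN}} \sum_{(i,j)} \big(d_{ij} - d^0_{ij}\big)^2,$$

where $d_{ij}$ is the current model distance and $d^0_{ij}$ the current
equilibrium distance of the restraint. The per-restraint spring constant is
absorbed into the single weight $w_{\mathrm{DEN}}$ — the strength knob the
method exposes. The total target is

$$E = E_{\mathrm{MM}} + w_{\mathrm{Xray}} E_{\mathrm{Xray}} + E_{\mathrm{DEN}},$$

with $E_{\mathrm{MM}}$ a stereochemical term and $E_{\mathrm{Xray}}$ a
least-squares amplitude residual over the work reflections.

At each temperature decrement of the slow-cooling schedule the equilibrium
distances are deformed once:

$$d^0_{ij} \leftarrow d^0_{ij} + \kappa\big[\gamma\,(d_{ij} - d^0_{ij}) +
(1-\gamma)\,(d^{\mathrm{ref}}_{ij} - d^0_{ij})\big].$$

The two limits are exactly honoured by the implementation and pinned by
tests: at frozen coordinates the update iterates to the fixed point
$d^{0*} = \gamma d + (1-\gamma) d^{\mathrm{ref}}$; at γ = 0 the deviation
from the reference distances contracts geometrically by $(1-\kappa)$ per
update; at γ = 1 the reference distances never enter the update, the network
tracks the refining model with a delay set by κ, and at convergence both the
DEN energy and its forces vanish — the restraints stop biasing the final
stationary point.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| γ | grid-searched (0–1, spacing 0.2) | 0 pins equilibria to the reference; 1 lets them track the model |
| w~DEN~ | grid-searched (3, 10, 30, 100, 300) | weight of the restraint term |
| κ | 0.1 | fraction of the deformation applied per temperature decrement |
| distance window | 3–15 Å | restraint eligibility, measured on the reference |
| sequence window | 0–10 residues | same-chain eligibility; lifted for inter-chain work |
| N | one per selected atom | restraint count (`n_restraints = "auto"`) |
| schedule | 3000 K → 0 K, −50 K, 6 steps, 4 fs | slow-cooling ladder (1.44 ps) |
| test fraction | 0.10 | cross-validation reflections |

The single-shot recommendation when the starting model is already close is
γ = 0 with w~DEN~ = 100. The macrocycle protocol defaults to eight cycles:
the first with nondeformable restraints (γ = 0) to relax the model safely,
then the chosen γ, and the final two cycles with w~DEN~ = 0 as a convergence
probe — the reported `drift` statistic (RMSD between the models after cycles
n−2 and n) flags refinements that have not reached a stable minimum. The
published protocol leaves the total macrocycle count open; eight
(1 + 5 + 2) is this package's default and is configurable.

Two B factors per residue (main chain: N, CA, C, O; side chain: the rest)
are refined by default, the standard parameterization when individual atomic
B factors would over-parameterize low-resolution data.

The number of restraints and the per-restraint force constant are never
stated in the published method; here `n_restraints = "auto"` selects one
restraint per restrained atom and the spring constant is unity (absorbed
into w~DEN~). Both are exposed in `selection_config()`.

## Choices where the design was open

**Cartesian, not torsion-angle, dynamics.** The published protocol uses
torsion-angle molecular dynamics; this package integrates Cartesian
velocity-Verlet dynamics with stiff bond and angle terms instead. This is a
deliberate simplification: the method's claims concern the restraint
dynamics, not the integrator. Consequence: the 4 fs step of the published
schedule is too long for stiff Cartesian bonds, so `refinement_config()`
defaults to a 1 fs step while `annealing_schedule()` keeps the published
constants (3000 K, −50 K, 6 × 4 fs = 1.44 ps) as the descriptive protocol
object. Temperature is controlled by per-level velocity rescaling, the
simplest scheme consistent with slow cooling.

**Update order.** Whether the original protocol deforms the equilibria
before or after a level's dynamics steps is unstated; this package updates
*after* (the literal reading of "at each temperature-decrement step") and
exposes `update_before_dynamics` to flip it.

**Stereochemistry.** $E_{\mathrm{MM}}$ is a reduced force field: harmonic
bonds (1000 kcal mol⁻¹ Å⁻²) and angles (100 kcal mol⁻¹ rad⁻²) with
equilibrium values taken from the fixture's own near-ideal geometry, plus a
purely repulsive quartic contact term switching on at 0.9× the sum of van
der Waals radii. No dihedrals, no electrostatics (customarily excluded from
crystallographic refinement anyway), no attractive dispersion. Nonbonded
exclusions cover pairs within three bonds (1-2, 1-3 and 1-4): with the 0.9×
contact radius, 1-4 pairs of an ideal peptide (e.g. O(i)–CA(i+1) at
≈ 2.75 Å) would otherwise register as clashes at build geometry, and
excluding 1-4 interactions from nonbonded terms is standard molecular-
mechanics practice.

**X-ray target.** Space group P1, one model per cell, a single overall
linear scale fitted in closed form on the work set, no bulk solvent, no
anisotropy, least squares rather than maximum likelihood. The synthetic
generator controls both sides of the comparison, so heavier crystallographic
machinery would add nothing to the method's claims. Form factors are a
one-Gaussian-plus-constant per element fit; observed and calculated
amplitudes use the same table, so refinement behaviour is independent of the
fit quality. Test-set reflections never touch the energy, the forces or the
scale — randomizing their amplitudes changes nothing but R~free~ (asserted
by test).

**Automatic w~Xray~.** The published method never specifies how the X-ray
weight is chosen. Here it is set by gradient-norm matching: w~Xray~ equalizes
the RMS per-atom X-ray and stereochemical forces, recomputed at each
macrocycle start. Freshly idealized starting models sit at a minimum of
$E_{\mathrm{MM}}$ where the matching ratio is ill-conditioned, so the probe
point is then taken from a short deterministic thermal burst of
stereochemistry-only dynamics — the same idea annealing refinement programs
use when they estimate the weight along a short trajectory.

**Rigid-body refinement and the P1 origin.** Segmented rigid-body
refinement optimizes one rotation-vector/translation pair per segment
(default: per chain), jointly, first against the d ≥ 2 d~min~ subset (wide
convergence basin) and then against all work reflections. In P1 the
amplitudes are invariant under a common translation of the whole model, so
pose recovery is meaningful — and is assessed in the tests — only modulo
that uniform origin shift.

## The synthetic module

Fixtures are ideal poly-alanine structures (5 heavy atoms per residue, L
chirality, φ = −57°, ψ = −47°): a single α-helix and parallel helix
bundles, centred in P1 boxes padded by ≥ 10 Å. Poly-alanine keeps atom
counts at desk scale while exercising every code path (chains, sequence
separation, main/side-chain grouping). Starting models are generated by
seeded random backbone torsion kicks propagated down-chain (bonded geometry
exactly preserved, then re-idealized) or by a smooth low-frequency Cartesian
displacement field, with the kick amplitude bisected until the coordinate
RMSD lands within 10% of the requested value. Observed amplitudes are
computed from the "true" structure and degraded with multiplicative
Gaussian noise; 5% relative noise is used in the benchmark scenarios, a
typical amplitude-error level for usable low-resolution data.

Three presets drive the end-to-end experiments: `lowres_helix` (20 residues,
start 2.5 Å from truth, data to 3.5 Å), `verylow_bundle` (3 × 12 residues,
chains rigidly displaced ~5°/2 Å then perturbed to ~4 Å total, data to
7.4 Å, inter-chain restraints with no sequence limit) and `register_shift`
(a 6-residue window threaded one residue off, reference better than start).

What these fixtures deliberately do not emulate: side-chain rotamers,
solvent scattering, experimental sigma models, space-group symmetry, and
model incompleteness. A passing benchmark therefore demonstrates the
mechanics and the cross-validation logic of the method on controlled data,
not its performance on deposited low-resolution datasets.

## Numerical choices

* Friedel-unique index sets keep the hemisphere whose first nonzero index is
  positive; (0,0,0) is excluded. |F(−h)| = |F(h)| is asserted on the full
  sphere.
* The closed-form work-set scale makes the amplitude target's gradient exact
  with the scale treated as constant (envelope theorem); all three force
  terms are checked against central finite differences at relative
  1e-4–1e-5, and the structure-factor kernel against an independently coded
  direct summation at 1e-8.
* The structure-factor kernels factor the phase into per-axis integer-power
  tables, so each (atom, reflection) term costs a few complex
  multiplications; energies are reproducible bitwise for a fixed seed.
* Velocity-Verlet at 1 fs conserves NVE energy to < 0.5% drift over 500
  steps on the helix fixture; per-level velocity rescaling then imposes the
  cooling ladder.
* Coincident restrained or bonded atoms, empty reflection sets, empty test
  sets, and out-of-range γ/κ/test-fraction values raise immediate errors
  rather than propagating NaNs.
* B factors are bounded to [1, 500] Å² during refinement; grouped refinement
  collapses each group into a complex partial structure factor so the
  objective scales with the number of groups.
* Sub-seeds for velocities, selections and grid cells derive from the master
  seed through a documented integer hash (`derive_seed`), making grid
  records independent of execution order.

## Problem sizes used by the shipped experiments

The packaged tests and the acceptance script run the full protocol at desk
scale: the `lowres_helix` benchmark uses a 4-macrocycle protocol (first
cycle γ = 0, last two released), a 3000 K → 0 K ladder in 200 K decrements
(15 levels × 6 × 1 fs per macrocycle) and 60 minimization steps, with the
reduced grid γ ∈ {0, 0.4, 1} × w~DEN~ ∈ {10, 100} × 3 repeats over five
seeded replicates. These sizes are the package's chosen benchmark
conditions; every protocol element of the full-size method is exercised.

## Known limitations

* Amplitude-only least squares; no maximum-likelihood σ~A~ weighting, no
  experimental-phase (MLHL) targets, no twinning.
* P1 only; no space-group symmetry, no bulk-solvent or anisotropic scaling.
* Cartesian dynamics in place of torsion-angle dynamics (see above); no
  constraint algorithms or thermostats beyond rescaling.
* The geometry score used for tie-breaking is an RMS bond + 0.1 × RMS angle
  deviation proxy, not Ramachandran/rotamer validation.
* Poly-alanine fixtures only; nucleic acids, ligands and alternate
  conformations are out of scope.
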