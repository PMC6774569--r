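---
title: "Methods: free-energy and structural analysis of G-quadruplex stacking dimers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free-energy and structural analysis of G-quadruplex stacking dimers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4stack)
```

## The scientific problem

Parallel-stranded G-quadruplexes (G4) expose their terminal guanine tetrads
to solvent and associate end-to-end by cofacial stacking. Two units can meet
in three orientations — 3'-3', 3'-5' and 5'-5' — and experiment consistently
finds the 5'-5' dimer dominant. Quantifying that preference requires (i)
free-energy profiles G(r) along the separation r of the two guanine-core
centres of mass, obtained by unbiasing umbrella-sampling windows; (ii) a
standard-state correction turning a profile into a dimerization free energy
at 1 M; (iii) an enthalpy decomposition identifying which structural
elements (backbones, tetrads, adenines, ions, water) drive or oppose
binding; and (iv) structural statistics of the dimer interface: phosphate
electrostatics, counterion binding, stacking geometry and conformational
clusters.

This package implements that analysis chain as reusable, tested components
and — because the underlying microsecond simulations are far outside desk
scale and no trajectories are deposited — ships a synthetic-data module that
generates every input class with known ground truth, so the whole pipeline
is validated by parameter recovery rather than by re-simulation. What the
passing tests demonstrate is therefore correctness of the *analysis
machinery* (unbiasing, quadrature, kernels, clustering) under controlled
conditions, not reproduction of the simulation-derived numbers themselves.

## Umbrella sampling and WHAM

Biased windows hold samples of r drawn under harmonic restraints
w_i(r) = k/2 (r − r_i)² with the simulation-standard force constant
k = 286.1 kcal/(mol·nm²) and 25 centres spaced 0.1 nm apart (defaults
1.1–3.5 nm; the window ladder is configurable). `whamSolve()` iterates the
standard self-consistent WHAM equations on binned histograms (default bin
width 0.02 nm, about five bins per window spacing) until the per-window free
energies f_i change by less than `tol` (default 10⁻⁶ kcal/mol). The profile
is anchored so that its mean over the unbound plateau (default 3.0–3.4 nm)
is zero, which is the reference the standard-state integral requires.
Replica exchange between windows is deliberately not emulated: once samples
are pooled per bias, WHAM is exchange-agnostic.

`whamWeights()` converts a converged solution into per-sample unbiased
weights (each sample weighted by the reciprocal of its summed biased
density), which downstream statistics — cluster populations, ensemble
averages, density grids — accept uniformly.

Errors come from `bootstrapProfile()`: a moving-block bootstrap within each
window whose block length is the integrated autocorrelation time of that
window's series (initial-positive-sequence estimator with a 2/√n noise
floor, so uncorrelated series get block length 1). This makes the errors
correlation-aware: duplicating every sample doubles the block length and
leaves the errors essentially unchanged.

## Standard-state dimerization free energy

The dimerization free energy at the 1 M standard state is

ΔG° = −k_B T ln[(1/V₀) ∫ exp(−G(r)/k_B T) dr],

with r expressed in Å, V₀ = 1661 ų (the volume per molecule at 1 M,
`standardVolume()` recomputes it from Avogadro's number as 1660.54 ų), and
the angular integrals cancelling the (4πr²)⁻¹ radial correction. Two
readings of this expression exist, because it is not stated whether G(r)
implicitly contains the radial Jacobian: the literal form above (default)
and a 4πr²-weighted variant (`jacobian = TRUE`), provided for sensitivity
analysis. The literal form reduces dimensionally to a length over a volume;
that tension is inherited from the printed expression and kept as-is rather
than silently "fixed".

Two implementation choices matter:

* The integral runs over the state's own range [r_lo, R] rather than
  literally from 0. For the deepest basin the two coincide (nothing is
  sampled below its lower boundary), but for higher basins the literal
  lower limit would double-count the deeper well and drive all state free
  energies to the same value. Per-basin ranges are the only reading under
  which separate G-mediated and A-mediated free energies of one profile
  make sense.
* Quadrature is the trapezoid rule on the profile bins; unsampled bins
  contribute zero. The square-well closed form (−10 kcal/mol over 1 Å gives
  ΔG° = −10 + k_B T ln 1661 = −5.58 kcal/mol) is matched to 10⁻³ kcal/mol
  and halving the bin width moves smooth-profile results by < 10⁻³
  kcal/mol.

Populations follow by Boltzmann weighting (`statePopulations()`, computed
with max-subtraction so very stable states cannot overflow). Feeding in the
five published dimerization free energies {6.4, −13.5, −11.7, −17.5, −8.6}
kcal/mol at 300 K returns 99.9% for the G-mediated 5'-5' state and 0.1% for
the G-mediated 3'-5' state after one-decimal rounding.

`assignStates()` detects basins on a 3-bin moving-average-smoothed profile:
local minima, merged when the separating barrier is below `minBarrier`
(default 0.5 kcal/mol), with boundaries and the integration limit R at the
flanking maxima, and the trailing plateau defined as the region within
0.5 kcal/mol of the profile's end level. A monotone profile has no bound
state; boundary bins are not minima.

## The planted landscape

`defaultLandscape()` is two Gaussian wells on a harmonic repulsive wall:
depth 20 kcal/mol at 1.1 nm (direct-stacking basin), depth 14 kcal/mol at
1.5 nm (mediated basin), wall below 1.0 nm, flat beyond ~2.9 nm — the
topography of a dimerization profile with a deep contact minimum, a
shallower mediated minimum and an unbound plateau, without copying any
unknown true values. The well widths (0.12 and 0.18 nm) are constrained by
umbrella-design feasibility: with k = 286.1 kcal/(mol·nm²) and 0.1 nm
window spacing, substantially narrower wells make the biased densities of
adjacent windows non-overlapping (the biased barrier region is suppressed
by ~e⁻¹⁶), and no histogram-based unbiasing could bridge the gap. The
chosen widths are close to the weakest curvature that still leaves two
clearly separated basins (barrier ≈ 1.9 kcal/mol between them).

`sampleWindows()` draws from the exact biased stationary density by
Metropolis Monte Carlo — dynamics are irrelevant for WHAM — with the step
size auto-tuned to 30–50% acceptance during a discarded burn-in. Samples
are serially correlated unless thinned (`thin`); the Kolmogorov–Smirnov
checks against analytic biased densities use thinned chains, while WHAM
recovery runs use unthinned chains plus the correlation-aware bootstrap.

Parameter recovery under the default conditions (25 windows, 5 × 10⁴
samples each, five seeds) gives an RMS profile error below 0.3 kcal/mol and
a deepest-basin ΔG° within 0.2 kcal/mol of the value computed from the
analytic landscape by the same quadrature.

## Nonbonded energetics and the enthalpy decomposition

A single energy kernel serves every energetic analysis, including the
counterion Monte Carlo of the toy builder: direct-sum Coulomb
(332.0636·q_iq_j/r_Å kcal/mol, i.e. 33.20636 in e²/nm units) plus 12-6
Lennard-Jones with Lorentz–Berthelot combination, minimum-image convention
when a box is present, and no cutoff or reciprocal-space term. Direct
summation is the only fully decomposable choice: group-pair energies are
exactly symmetric, superposable over disjoint groups, and sum to the total.
It is a known systematic difference from mesh-Ewald electrostatics used in
the simulations themselves.

`enthalpyMatrix()` averages all group-pair energies over a bound and an
unbound ensemble (honouring unbiased frame weights; plain averages are a
degenerate case with uniform weights) and reports the difference per pair,
with intra-group changes on the diagonal. The conservation identity — the
matrix total equals the single-pass total energy change — is enforced to
10⁻⁶ relative in the tests. `phosphateEnergyDensity()` resolves phosphate
selections into per-residue PO₄ units, bins the cross-strand Coulomb energy
by P–P distance (phosphorus-atom distance by default, centre-of-mass as an
option) and attaches the cumulative repulsion curve, whose endpoint equals
the total cross-strand phosphate electrostatics.

## Geometry

Order parameters are computed per frame: core separation (mass-weighted
COM distance), orientation angle between total-least-squares tetrad planes
with normals oriented outward from each unit's core (so facing tetrads of a
stacked dimer read 180°), interface shift (in-plane distance between the
two unit axes' intersections with the interface plane, the axes joining
each unit's external-tetrad COMs), and backbone twist offset (circular-mean
ring phase in 4-fold symmetry space, reduced modulo the 90° period, so a
construction at 100° reads 10°). Contact areas are projected-footprint
overlaps: atoms become van der Waals disks on the interface plane,
rasterized at 0.01 nm with the raster origin offset by an irrational cell
fraction to avoid alignment bias; the default interface normal is the line
joining the two selections' centres (supply `normal=` when the facing
plates coincide). This footprint definition is a declared choice validated
by internal oracles only — the published contact-area values were computed
by an unstated method and are not comparison targets.

## Ion atmosphere and clustering

Ion contacts use minimum atom–atom distances with a 0.7 nm cutoff: "all"
ions touch either backbone, "interface" ions touch both simultaneously,
"interface PO₄" ions touch both phosphate sets; containment
(interface_po4 ≤ interface ≤ all) holds by construction. Density grids
superpose frames by Kabsch alignment, bin selected atoms (0.05 nm default
voxels) and normalize so the integral equals the mean atom count per frame.
Site detection thresholds the grid at a multiple (default 10×) of a
user-supplied bulk density and integrates 26-connected components; the
threshold is an exposed parameter because published site counts depend on
an unstated one. RDFs normalize by 4πr²dr shells and the ideal-gas target
density (box volume, or an explicit sampling volume for non-periodic toys).

Clustering is the hybrid k-centers/k-medoids procedure under superposed
RMSD with a 0.3 nm cutoff: k-centers seeds with frame 1 and adds the
farthest frame until the covering radius is within the cutoff (this
guarantee is asserted on the stage-1 assignment), then k-medoids refines
labels and medoids against the weighted within-cluster RMSD sum. All ties
break toward the lowest frame index, making the procedure fully
deterministic; populations are sums of unbiased frame weights.

## Toy dimers and planted ensembles

`buildToyDimer()` creates two rigid coarse-grained units — three stacked
4-bead tetrad planes (0.35 nm rise), a 12-bead phosphate ring (radius
1.0 nm, charge −1 e per bead) with exact 4-fold symmetry, three terminal
adenine beads beyond the 5' plane — placed per stacking mode, separation
and twist. The phosphate ring's per-level helical advance defaults to 0°:
a ±120° advance in 4φ-space cancels the circular mean and would leave the
ring without a well-defined global phase. Counterions (+1 e) are
equilibrated by Metropolis against the fixed charges using the same energy
kernel as the decomposition, with recorded frames separated by many sweeps.
These toys reproduce the *geometric logic* of the dimer interface (like-
charge ring repulsion, twist-dependent P–P distances, ion localization);
they do not attempt realistic DNA geometry, explicit solvent or force-field
fidelity, and conclusions about real G4 DNA should not be read off them.

`plantClusters()` perturbs medoid conformations with isotropic Gaussian
noise and random rigid-body motions; because the cluster metric is RMSD
after superposition, planted medoids must differ in internal shape (not
merely by placement) to constitute distinct clusters.

## Pipeline, problem sizes and determinism

`validateConfig()`/`runPipeline()` orchestrate the stages
(synthesis → WHAM → states → ΔG° → populations → decomposition → geometry →
ions → clustering) from a YAML config with strict unknown-key rejection and
the physical defaults quoted above (T = 300 K, k_B = 0.0019872041
kcal/(mol·K), V₀ = 1661 ų, cutoffs 0.7/0.3 nm, plateau 3.0–3.4 nm). Every
random stage derives from the config seed; rerunning with the same seed
reproduces the report byte-for-byte apart from timestamps. A failed stage
returns the partial report with the failure recorded. Reports are validated
against the JSON schema shipped in `inst/schema/`.

The default test and pipeline runs use deliberately modest problem sizes —
10³–10⁴ Metropolis samples per window, a handful of toy-dimer frames,
tens of planted conformations — chosen so the whole suite exercises every
code path in well under a minute of sampling; the headline recovery runs
use the full 25-window, 5 × 10⁴-sample design.

## Known limitations

* Direct-sum electrostatics differ systematically from Ewald-based
  simulation energetics; decomposition entries are meaningful relative to
  each other, not as absolute reproductions of published matrices.
* The WHAM estimator is histogram-based; a binless estimator (MBAR) is
  out of scope except as a possible cross-check.
* Published simulation-derived magnitudes (profile depths, ΔH matrices,
  ion counts, site counts) require the original microsecond trajectories
  and are not desk-scale reproducible; only their printed worked examples
  (populations, gaps, the standard volume, the closed-form oracle) are
  asserted numerically.
* Orthorhombic boxes only; binary trajectory formats (XTC/DCD) are not
  read in this release.
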