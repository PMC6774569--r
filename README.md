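# g4stack

Free-energy and structural analysis of end-to-end stacking (dimerization)
of parallel-stranded G-quadruplexes (G4).

Solvent-exposed terminal G-tetrads let parallel G-quadruplexes associate by
cofacial stacking in three orientations (3'-3', 3'-5', 5'-5'), and the
5'-5' dimer dominates in experiment. Deciding *why* requires the full
analysis chain behind biased molecular simulation studies of the process:
unbiasing umbrella-sampling windows into a free-energy profile G(r) along
the separation of the two guanine cores, converting basins of that profile
into standard-state dimerization free energies and equilibrium populations,
decomposing the dimerization enthalpy into group-pair nonbonded
contributions, profiling the interphosphate electrostatic repulsion and the
counterion atmosphere that screens it, and clustering the dimeric ensemble.
`g4stack` implements that chain for computational biophysicists as tested,
reusable R components, plus synthetic-data generators with known ground
truth so every stage is validated by parameter recovery — no simulation
output or download is needed.

## The core quantities

WHAM combines biased window histograms (harmonic bias w_i(r) = k/2
(r − r_i)², default k = 286.1 kcal/(mol·nm²), 25 windows spaced 0.1 nm)
into G(r), anchored to a zero-mean unbound plateau. Each basin's
standard-state dimerization free energy is

&nbsp;&nbsp;&nbsp;&nbsp;ΔG°(dim) = −k_B·T · ln[ (1/V₀) ∫ exp(−G(r)/k_B·T) dr ]

with r in Å and V₀ = 1661 ų (the 1 M volume per molecule; an optional
4πr² Jacobian variant is provided). Populations are Boltzmann weights of
the ΔG° values. The enthalpy decomposition averages the direct-sum
Coulomb + Lennard-Jones energy of every group pair over bound and unbound
(optionally WHAM-weighted) ensembles; conformational clustering is the
hybrid k-centers/k-medoids algorithm under superposed RMSD with a 0.3 nm
cutoff. The methods vignette (`vignettes/g4stack-methods.Rmd`) documents
every model choice, default and limitation.

## Worked example

Recover a planted double-well landscape from synthetic umbrella windows,
define states, and compute standard-state free energies and populations:

```r
library(g4stack)

landscape <- defaultLandscape()               # wells at 1.1 and 1.5 nm
windows <- sampleWindows(landscape, nPerWindow = 20000, seed = 1)
sol <- whamSolve(windows)
sol$profile
#> FreeEnergyProfile: 129 bins (1.030-3.590 nm), min G = -21.40 kcal/mol, anchor: plateau:3-3.4

states <- assignStates(sol$profile)
results <- lapply(states, function(s) standardStateDG(sol$profile, s))
pops <- statePopulations(results)
for (i in seq_along(results)) {
  results[[i]]@population <- pops[[i]]
  show(results[[i]])
}
#> Standard-state dG(dim) [I]: -16.64 +/- NA kcal/mol (T = 300 K, V0 = 1661 A^3), population 100.0%
#> Standard-state dG(dim) [II]: -9.68 +/- NA kcal/mol (T = 300 K, V0 = 1661 A^3), population 0.0%
```

State I is the deep direct-stacking basin near 1.1 nm (here recovered at
−16.6 kcal/mol, within 0.2 kcal/mol of the value obtained by quadrature on
the analytic landscape); state II is the shallower mediated basin near
1.5 nm, essentially unpopulated at equilibrium. Errors come from
`bootstrapProfile()` (correlation-aware moving-block bootstrap).

Boltzmann-weighting the five published dimerization free energies of the
three stacking modes reproduces the published equilibrium populations:

```r
round(100 * statePopulations(c(`3-3 G` = 6.4, `3-5 G` = -13.5,
  `3-5 A` = -11.7, `5-5 G` = -17.5, `5-5 A` = -8.6)), 1)
#> 3-3 G 3-5 G 3-5 A 5-5 G 5-5 A
#>   0.0   0.1   0.0  99.9   0.0
```

The same machinery drives toy-dimer energetics (`buildToyDimer()`,
`enthalpyMatrix()`, `phosphateEnergyDensity()`), interface geometry
(`comDistance()`, `orientationAngle()`, `shiftCoordinate()`,
`twistOffset()`, `contactArea()`), ion statistics (`ionContactCounts()`,
`densityGrid()`, `siteOccupancy()`, `rdf()`) and clustering
(`clusterEnsemble()`). `runPipeline(validateConfig("config.yml"))` runs
the whole chain from a YAML config and returns a schema-validated,
seed-deterministic report (see `inst/extdata/example-config.yml`).

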