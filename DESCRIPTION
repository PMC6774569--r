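Package: g4stack
Title: Free-Energy and Structural Analysis of G-Quadruplex Stacking Dimers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis machinery for end-to-end stacking (dimerization) of
    parallel-stranded G-quadruplexes studied by biased molecular simulation.
    Provides WHAM unbiasing of umbrella-sampling windows into free-energy
    profiles with correlation-aware bootstrap errors, standard-state
    dimerization free energies and equilibrium state populations, pairwise
    nonbonded interaction-enthalpy decomposition between structural elements,
    phosphate-phosphate electrostatic energy-density profiles, geometric
    order parameters (core separation, orientation angle, interface shift,
    backbone twist offset), ion-atmosphere statistics (contact counts, 3-D
    density grids, site occupancies, radial distribution functions), and
    weighted k-centers/k-medoids conformational clustering. A synthetic-data
    module generates every input class with known ground truth: Metropolis
    sampling of biased windows over planted free-energy landscapes, toy
    coarse-grained quadruplex dimers with charged phosphate rings and mobile
    counterions, and conformational ensembles with planted cluster structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, yaml, bio3d
Suggests: testthat (>= 3.0.0), mclust, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
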