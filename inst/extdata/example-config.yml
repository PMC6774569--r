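# Example pipeline configuration. Omitted keys take the documented
# defaults (T = 300 K, V0 = 1661 A^3, k = 286.1 kcal/(mol nm^2),
# ion-contact cutoff 0.7 nm, cluster RMSD cutoff 0.3 nm, plateau 3.0-3.4 nm).
seed: 1
nPerWindow: 2000
bootstrap:
  replicates: 0   # >= 20 enables bootstrap errors on the profile
dimer:
  mode: "5-5"
  separation: 1.1
  twist: 45
  nIons: 6
  nFrames: 5
stages: [synth, wham, states, dg, populations, decompose, geometry, ions, cluster]
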