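# Sidecar nonbonded parameter table for the coarse toy-dimer beads.
# Columns: resname atomname charge_e sigma_nm epsilon_kcal mass_amu radius_nm
resname atomname charge_e sigma_nm epsilon_kcal mass_amu radius_nm
PHO P   -1.0 0.40 0.15  95.0  0.21
GUA GB   0.0 0.35 0.10 150.0  0.20
ADE AB   0.0 0.35 0.10 134.0  0.20
K   K    1.0 0.30 0.10  39.1  0.28
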