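# Packaged coil dihedral library.
# Format: residue class -> list of [phi, psi, weight] (degrees; weights sum
# to 1 per class).  Classes: generic, gly (glycine), pro (proline), prepro
# (residue immediately before a proline).  Basins follow the standard coil
# regions of the Ramachandran map (beta, polyproline-II, alpha-R, alpha-L);
# weights were chosen so that sampled chains reproduce the experimental
# excluded-volume scaling of denatured/disordered proteins.  The file is
# user-replaceable via read_dihedral_library().
generic:
- [-135.0, 135.0, 0.16]
- [-120.0, 125.0, 0.10]
- [-145.0, 150.0, 0.09]
- [-75.0, 145.0, 0.16]
- [-65.0, 150.0, 0.10]
- [-85.0, 140.0, 0.06]
- [-63.0, -43.0, 0.14]
- [-70.0, -35.0, 0.07]
- [-90.0, -10.0, 0.04]
- [55.0, 45.0, 0.05]
- [-150.0, 80.0, 0.03]
gly:
- [-80.0, 170.0, 0.15]
- [80.0, -170.0, 0.15]
- [-90.0, 10.0, 0.12]
- [90.0, -10.0, 0.12]
- [175.0, 175.0, 0.10]
- [-65.0, -40.0, 0.12]
- [65.0, 40.0, 0.12]
- [-150.0, 150.0, 0.12]
pro:
- [-63.0, 150.0, 0.55]
- [-63.0, -35.0, 0.35]
- [-75.0, 160.0, 0.10]
prepro:
- [-135.0, 140.0, 0.40]
- [-70.0, 150.0, 0.40]
- [-65.0, -40.0, 0.20]
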