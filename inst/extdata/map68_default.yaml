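# Default mapping from the standard 68-point detector scheme to the
# 18-landmark anatomical configuration. Indices are 0-based in the detector
# convention. 15 landmarks map directly; glabella and the two palpebrale
# inferius points are computed as midpoints. Edit or replace this table (see
# read_mapping()) if your detector or annotation scheme differs.
- target: glabella
  midpoint_of: [21, 22]
- target: sellion
  source: 27
- target: endocanthion_r
  source: 39
- target: endocanthion_l
  source: 42
- target: exocanthion_r
  source: 36
- target: exocanthion_l
  source: 45
- target: palpebrale_inferius_r
  midpoint_of: [40, 41]
- target: palpebrale_inferius_l
  midpoint_of: [46, 47]
- target: pronasale
  source: 30
- target: subnasale
  source: 33
- target: subalare_r
  source: 31
- target: subalare_l
  source: 35
- target: labiale_superius
  source: 51
- target: labiale_inferius
  source: 57
- target: crista_philtri_r
  source: 50
- target: crista_philtri_l
  source: 52
- target: chelion_r
  source: 48
- target: chelion_l
  source: 54
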