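name: fumarate
sites:
- label: H2
  shift_ppm: 6.51999999999999957
  xyz_angstrom:
  - -0.59093335299130434
  - 0.90995756622078494
  - 0.0
- label: H3
  shift_ppm: 6.51999999999999957
  xyz_angstrom:
  - 1.92093335299130441
  - -0.90995756622078494
  - 0.0
couplings:
- - H2
  - H3
  - 15.80000000000000071
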