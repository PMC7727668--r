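name: Asn
sites:
- label: Hb2
  shift_ppm: 2.94899999999999984
  xyz_angstrom:
  - -0.36129973706051877
  - 0.51095498823281893
  - 0.88500000000000001
- label: Hb3
  shift_ppm: 2.86299999999999999
  xyz_angstrom:
  - -0.36129973706051877
  - 0.51095498823281893
  - -0.88500000000000001
- label: Ha
  shift_ppm: 4.00600000000000023
  xyz_angstrom:
  - 1.88933333333333331
  - -0.51383092766222438
  - 0.88998127321122145
couplings:
- - Hb2
  - Hb3
  - -13.55000000000000071
- - Hb2
  - Ha
  - 5.65000000000000036
- - Hb3
  - Ha
  - 1.6399999999999999
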