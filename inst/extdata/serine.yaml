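name: Ser
sites:
- label: Hb2
  shift_ppm: 3.96200000000000019
  xyz_angstrom:
  - -0.36129973706051877
  - 0.51095498823281893
  - 0.88500000000000001
- label: Hb3
  shift_ppm: 3.8879999999999999
  xyz_angstrom:
  - -0.36129973706051877
  - 0.51095498823281893
  - -0.88500000000000001
- label: Ha
  shift_ppm: 3.83400000000000007
  xyz_angstrom:
  - 1.88933333333333331
  - -0.51383092766222438
  - 0.88998127321122145
couplings:
- - Hb2
  - Hb3
  - -10.51999999999999957
- - Hb2
  - Ha
  - 4.80999999999999961
- - Hb3
  - Ha
  - 1.32000000000000006
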