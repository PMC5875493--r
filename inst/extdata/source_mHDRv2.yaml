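name: mHDRv2
radionuclide: Ir-192
mode: line
Sk_U: 27076.0
Lambda_cGy_per_hU: 1.108
active_length_cm: 0.36
dwell_time_h: 0.333333333333333
radial_dose:
- r: 1.0
  g: 1.0
- r: 2.0
  g: 1.007
- r: 3.0
  g: 1.008
- r: 4.0
  g: 1.004
- r: 5.0
  g: 0.995
geometry_ratio:
- r: 1.0
  ratio: 1.0
- r: 2.0
  ratio: 0.256
- r: 3.0
  ratio: 0.115
- r: 4.0
  ratio: 0.065
- r: 5.0
  ratio: 0.041
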