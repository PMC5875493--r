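name: VS2000
radionuclide: Ir-192
mode: line
Sk_U: 27292.0
Lambda_cGy_per_hU: 1.101
active_length_cm: 0.5
dwell_time_h: 0.333333333333333
radial_dose:
- r: 1.0
  g: 1.0
- r: 2.0
  g: 1.005
- r: 3.0
  g: 1.006
- r: 4.0
  g: 1.002
- r: 5.0
  g: 0.993
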