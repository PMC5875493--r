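name: '6711'
radionuclide: I-125
mode: point
Sk_U: 1.01
Lambda_cGy_per_hU: 0.965
half_life_h: 1425.599999999999909
radial_dose:
- r: 1.0
  g: 1.0
- r: 2.0
  g: 0.819
- r: 3.0
  g: 0.636
- r: 4.0
  g: 0.499
- r: 5.0
  g: 0.367
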