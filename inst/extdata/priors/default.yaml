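# Calibrated operational prior (trial defaults).
prior:
  tox_mean: [-3.0, 1.1]
  tox_var: [25.0, 4.0]
  eff_mean: [-1.0, 1.1, -5.0, -0.1]
  eff_var: [6.0, 2.0, 3.0, 2.0]
  tau_loc: 0.8
  tau_scale: 1.0
  tau_bounds: [0.0, 1.5]
  frailty_scale: 1.0
  weight_a: 1.0
  weight_b: 1.0
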