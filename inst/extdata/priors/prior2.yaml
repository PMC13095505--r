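# Sensitivity prior 2: alternative dose-efficacy coefficient priors,
# gamma0 ~ N(-2, 5^2), gamma1 ~ N(1, 1^2), gamma2 ~ N(-5, 3^2),
# gamma3 ~ N(-1, 2^2); everything else at default.
prior:
  eff_mean: [-2.0, 1.0, -5.0, -1.0]
  eff_var: [25.0, 1.0, 9.0, 4.0]
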