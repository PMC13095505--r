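# Sensitivity prior 1: alternative dose-toxicity coefficient prior,
# beta0 ~ N(-4, 4^2), beta1 ~ N(1.1, 2^2); everything else at default.
prior:
  tox_mean: [-4.0, 1.1]
  tox_var: [16.0, 4.0]
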