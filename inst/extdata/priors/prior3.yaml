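# Sensitivity prior 3: borrowing weight prior Beta(0.5, 0.5) instead of
# Beta(1, 1).
prior:
  weight_a: 0.5
  weight_b: 0.5
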