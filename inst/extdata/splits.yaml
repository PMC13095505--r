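# Alternative stage sample-size splits studied in sensitivity analyses.
# Primary two-stage split:   18/24 (N = 42)
# Alternatives:              24/24 (N = 48), 18/36 (N = 54)
# Three-stage split:         15/15/24 (N = 54)
splits:
  primary: [18, 24]
  equal: [24, 24]
  late_heavy: [18, 36]
  three_stage: [15, 15, 24]
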