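# Alternative frailty hyper-prior: Half-Cauchy(0, 1) on the frailty
# VARIANCE (lighter tail on the SD) instead of on the SD.
prior:
  frailty_prior: var
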