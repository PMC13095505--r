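# Sensitivity: Student-t patient frailty (heavier tails), scale-
# parameterized with df = 5.
prior:
  frailty: student_t
  frailty_df: 5
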