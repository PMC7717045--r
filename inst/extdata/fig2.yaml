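# two-rate sign-changing benchmark: smooth travelling wave experiment
d_i: 0.25
d_g: 0.05
lam: 0.75
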