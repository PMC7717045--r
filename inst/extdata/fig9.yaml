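# quadratic diffusivity (u - 0.1)(u - 0.3): shock-fronted wave experiment
poly_coef: [0.03, -0.4, 1.0]
lam: 0.75
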