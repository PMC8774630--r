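# Low-dimensional Gaussian mixture dictionary, scenario 2 (W = 7)
family: gaussian
mean: [0, 1, 2, 3, 4, 5, 6]
sd: [0.3, 0.2, 0.2, 0.1, 0.2, 0.2, 0.3]
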