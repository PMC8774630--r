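# Low-dimensional Gaussian mixture dictionary, scenario 1 (W = 6)
family: gaussian
mean: [0, 10, 20, 30, 40, 50]
sd: [1, 2, 3, 4, 5, 6]
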