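# Example qsnoise configuration: gamma2 operating point with strong diffusion.
# Keys: alpha, beta, k_minus, D (or D_t), k_plus, N, r, V, target_mean_nM, preset
preset: gamma2
D_t: 100
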