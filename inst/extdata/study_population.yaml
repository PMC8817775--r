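# Mixed-logit preference weights of the community-based DOT study:
# coefficient means (mu) and heterogeneity SDs (sigma) for the ASC and the
# five dummy-coded attribute levels. The ASC is fixed (sigma = 0).
labels: [asc, c_chw, c_expert, l_home, s_phcall, s_tvouch]
mu: [0.52, 1.13, 0.89, 1.25, 0.70, 1.35]
sigma: [0.0, 1.85, 1.77, 1.19, 0.19, 0.55]
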