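# validation run: conjugate normal model with analytic marginal likelihood
model = normal_conjugate
stones = 30
alpha = 0.3
iterations = 2000
thinning = 4
burnin_frac = 0.25
preburn_iters = 500
seed = 1
workers = 1
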