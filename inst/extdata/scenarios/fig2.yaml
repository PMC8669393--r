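# Price vs quality-preference sweep scenario.
# Market parameterization a = 0.3, b = 0.3, gamma = 10; c is the swept
# variable. Stage-2 solver runs in as_printed price-response mode.
schema_version: 1
preset: fig2
market: {a: 0.3, b: 0.3, c: 0.6, gamma: 10.0, F: 0.0}
bargaining: {theta1: 0.5, theta2: 0.5, convention: split, first_proposer: alliance}
insurance: {delta: 0.1, R: 1.0, sigma2: 1.0}
stage2_mode: as_printed
sweep: {variable: c, lo: 0.1, hi: 1.2, n_points: 23}
seed: 1
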