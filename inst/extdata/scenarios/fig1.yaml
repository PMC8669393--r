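# Price vs price-sensitivity-of-demand sweep scenario.
# Market parameterization a = 0.3, gamma = 10, c = 0.6; b is the swept
# variable (baseline 0.3). The sweep range is a package choice: the source
# scenario states no axis range, so an admissible range is used.
schema_version: 1
preset: fig1
market: {a: 0.3, b: 0.3, c: 0.6, gamma: 10.0, F: 0.0}
bargaining: {theta1: 0.5, theta2: 0.5, convention: split, first_proposer: alliance}
insurance: {delta: 0.1, R: 1.0, sigma2: 1.0}
stage2_mode: as_printed
sweep: {variable: b, lo: 0.05, hi: 0.6, n_points: 23}
seed: 1
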