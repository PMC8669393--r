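# Welfare-loss vs co-payment-ratio contrast scenario.
# b < a so the risk-aversion threshold R_crit = delta*p_bar*(a-b)/sigma2 is
# positive and a contrastive low/high risk-aversion pair exists; p_bar is
# supplied directly (standalone insurance-stage scenario).
schema_version: 1
preset: fig3
market: {a: 0.3, b: 0.15, c: 0.6, gamma: 10.0, F: 0.0}
bargaining: {theta1: 0.5, theta2: 0.5, convention: split, first_proposer: alliance}
insurance: {delta: 0.1, R: 1.0, sigma2: 1.0, p_bar: 2.0}
stage2_mode: as_printed
sweep: {variable: lambda, lo: 0.0, hi: 1.0, n_points: 101}
seed: 1
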