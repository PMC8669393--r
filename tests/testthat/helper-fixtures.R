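# Shared fixtures for the suite. All randomness is seeded; fixture draws go
# through generate_fixtures() so unit and acceptance tests exercise the same
# admissible-parameter sampler.

fig1_market <- function() market_params(a = 0.3, b = 0.3, c = 0.6, gamma = 10, F = 0)

# n random admissible (p, q) points for a market: q in [0, 1], p below the
# choke price at that quality, so Q >= 0 by construction.
random_admissible_points <- function(params, n, seed = 1) {
  set.seed(seed)
  q <- runif(n, 0, 1)
  p <- runif(n) * (params$a + params$c * q) / params$b
  data.frame(p = p, q = q)
}
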