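test_that("demand, inverse demand and cost follow the linear market model", {
  mp <- fig1_market()
  expect_equal(demand(mp, p = 1, q = 1), 0.6)
  expect_equal(demand(mp, p = mp$a / mp$b, q = 0), 0)
  # quality-independence when c = 0
  mp0 <- market_params(0.3, 0.3, 0, 10)
  expect_equal(demand(mp0, 0.7, q = 5), demand(mp0, 0.7, q = 0))

  expect_equal(inverse_demand(mp, Qv = 0, q = 0), mp$a / mp$b)
  expect_equal(inverse_demand(mp, Qv = 0.6, q = 1), 1)
  expect_equal(inverse_demand(mp, demand(mp, 0.7, 0.2), q = 0.2), 0.7)

  expect_equal(total_cost(market_params(1, 1, 1, 5, F = 0), q = 0, Qv = 3), 0)
  expect_equal(total_cost(market_params(1, 1, 1, 10, F = 1), 0.2, 0.5), 1.1)
  # non-decreasing in quantity and quality
  expect_gte(total_cost(mp, 0.2, 0.6), total_cost(mp, 0.2, 0.5))
  expect_gte(total_cost(mp, 0.3, 0.5), total_cost(mp, 0.2, 0.5))
  expect_error(total_cost(mp, -0.1, 1), "non-negative")
})

test_that("parameter validation rejects degenerate markets", {
  expect_error(market_params(0.3, 0, 0.6, 10), "strictly positive")
  expect_error(market_params(-1, 0.3, 0.6, 10), "non-negative")
  expect_error(market_params(0.3, 0.3, 0.6, 0), "gamma")
  expect_error(market_params(0.3, 0.3, 0.6, 10, F = -1), "'F'")
  expect_error(demand(fig1_market(), NA_real_, 1), "non-finite")
})

test_that("profit matches (p - mc)Q - F in all regimes", {
  mp <- market_params(0.3, 0.3, 0.6, 10, F = 0)
  expect_equal(profit(mp, p = 1, q = 1), (1 - 5) * 0.6)
  # marginal-cost pricing earns -F for any quality
  mpF <- market_params(0.3, 0.3, 0.6, 10, F = 2)
  for (q in c(0, 0.2, 0.7)) {
    expect_equal(profit(mpF, p = 0.5 * 10 * q^2, q = q), -2)
  }
  # zero demand earns -F
  q0 <- 0.1
  p0 <- (mpF$a + mpF$c * q0) / mpF$b
  expect_equal(profit(mpF, p0, q0), -2)
})

test_that("patient utility equals the linear-demand consumer surplus Q^2/(2b)", {
  mp <- fig1_market()
  pts <- random_admissible_points(mp, 50, seed = 11)
  for (i in seq_len(nrow(pts))) {
    Q <- demand(mp, pts$p[i], pts$q[i])
    expect_equal(patient_utility(mp, pts$p[i], pts$q[i]), Q^2 / (2 * mp$b))
  }
  # arithmetic: b = 0.3, Q = 0.6 -> 0.6 (p = 1, q = 1)
  expect_equal(patient_utility(mp, 1, 1), 0.6)
  # quadrature cross-check of the closed-form integral
  p <- 0.5; q <- 0.3
  Q <- demand(mp, p, q)
  up_quad <- stats::integrate(function(t) inverse_demand(mp, t, q), 0, Q,
                              rel.tol = 1e-12)$value - p * Q
  expect_equal(patient_utility(mp, p, q), up_quad, tolerance = 1e-10)
  # inadmissible points error
  expect_error(patient_utility(mp, p = 2, q = 0), "inadmissible")
})

test_that("social welfare is consumer plus producer surplus (transfers cancel)", {
  mp <- fig1_market()
  pts <- random_admissible_points(mp, 100, seed = 3)
  for (i in seq_len(nrow(pts))) {
    wf <- social_welfare(mp, pts$p[i], pts$q[i])
    expect_equal(wf,
                 patient_utility(mp, pts$p[i], pts$q[i]) +
                   profit(mp, pts$p[i], pts$q[i]),
                 tolerance = 1e-12)
    expect_gte(patient_utility(mp, pts$p[i], pts$q[i]), 0)
  }
  expect_equal(social_welfare(mp, 1, 1), 0.6 - 2.4)
  mpF <- market_params(0.3, 0.3, 0.6, 10, F = 0.5)
  expect_equal(social_welfare(mpF, p = mpF$a / mpF$b, q = 0), -0.5)
})

test_that("welfare price gradient is -b(p - mc): marginal-cost pricing is optimal", {
  mp <- fig1_market()
  pts <- random_admissible_points(mp, 20, seed = 5)
  h <- 1e-6
  for (i in seq_len(nrow(pts))) {
    p <- pts$p[i] * 0.9 + 0.01 # keep the stencil inside the admissible region
    q <- pts$q[i]
    num <- (social_welfare(mp, p + h, q) - social_welfare(mp, p - h, q)) / (2 * h)
    expect_equal(num, -mp$b * (p - 0.5 * mp$gamma * q^2), tolerance = 1e-6)
  }
})

test_that("objective_values and admissibility_flags summarize a point", {
  mp <- fig1_market()
  ov <- objective_values(mp, 0.5, 0.2)
  expect_equal(ov$WF, ov$Up + ov$profit)
  fl <- admissibility_flags(mp, 0.5, 0.2)
  expect_named(fl, c("Q", "p", "q", "profit"))
  expect_true(all(fl[c("Q", "p", "q")]))
  expect_false(all(admissibility_flags(mp, 2, 0)[["Q"]]))
})
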