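test_that("stage-1 quality best response solves its quadratic FOC exactly", {
  mp <- fig1_market()
  # linear term vanishes at p = a/b: 9 q^2 = 0.6 -> q = sqrt(1/15)
  expect_equal(follower_quality_response(mp, 1), sqrt(1 / 15),
               tolerance = 1e-10)
  expect_equal(follower_quality_response(mp, 0), 0)
  expect_equal(follower_quality_response(market_params(0.3, 0.3, 0, 10), 2), 0)
  expect_error(follower_quality_response(mp, -0.1), "non-negative")

  fx <- generate_fixtures(101, 20)
  for (f in fx) {
    m <- f$market
    p <- 0.5 * m$a / m$b
    q <- follower_quality_response(m, p)
    foc <- 1.5 * m$c * m$gamma * q^2 + m$gamma * (m$a - m$b * p) * q - m$c * p
    expect_lt(abs(foc), 1e-10)
    # q is the numeric argmax of profit over a quality grid
    grid <- seq(0, 3 * q + 0.5, length.out = 2001)
    vals <- profit(m, p, grid)
    expect_lt(abs(grid[which.max(vals)] - q), diff(grid[1:2]) + 1e-12)
  }
})

test_that("alliance price response: derived mode is marginal-cost pricing", {
  mp <- fig1_market()
  expect_equal(alliance_price_response(mp, 0.2, "derived"), 0.2)
  # social welfare is maximized over p at the derived response (grid argmax)
  for (q in c(0.1, 0.3, 0.5)) {
    p_star <- alliance_price_response(mp, q, "derived")
    grid <- seq(0, (mp$a + mp$c * q) / mp$b, length.out = 4001)
    vals <- vapply(grid, function(p) social_welfare(mp, p, q), numeric(1))
    expect_lt(abs(grid[which.max(vals)] - p_star), diff(grid[1:2]) + 1e-12)
  }
  # literal parse, quarantined behind the mode flag: can go negative
  expect_equal(alliance_price_response(mp, 1, "as_printed"),
               0.3 + 0.6 + (0.3 - 1) / 0.3)
})

test_that("stage-1 solver agrees with the brute-force grid oracle", {
  mp <- fig1_market()
  sol <- solve_stage1(mp)
  oracle <- brute_force_equilibrium(mp, "alliance", n_grid = 1001)
  step <- oracle$solver_meta$step
  expect_lt(abs(sol$p - oracle$p), step + 1e-12)
  expect_true(sol$interior)
  expect_lt(sol$leader_foc_residual, 1e-6)
  expect_lt(sol$follower_foc_residual, 1e-10)
  expect_true(all(sol$admissible))
  expect_equal(sol$Q, demand(mp, sol$p, sol$q))
  # follower cannot gain by unilateral quality deviation
  grid <- seq(0, 2 * sol$q + 0.2, length.out = 1001)
  expect_lte(max(profit(mp, sol$p, grid)), profit(mp, sol$p, sol$q) + 1e-9)
})

test_that("stage-2 derived mode detects the flat-profit degeneracy", {
  for (f in generate_fixtures(5, 5)) {
    sol <- solve_stage2(f$market, mode = "derived")
    expect_true(sol$degenerate)
    expect_lt(sol$solver_meta$objective_spread, 1e-9)
    expect_equal(sol$objectives$profit, -f$market$F)
    # follower optimality: welfare cannot be raised by changing the price
    grid <- seq(0, (f$market$a + f$market$c * sol$q) / f$market$b,
                length.out = 501)
    wf <- vapply(grid, function(p) social_welfare(f$market, p, sol$q),
                 numeric(1))
    expect_lte(max(wf), social_welfare(f$market, sol$p, sol$q) + 1e-9)
  }
})

test_that("stage-2 as_printed solver matches the grid oracle", {
  for (f in generate_fixtures(23, 10)) {
    sol <- solve_stage2(f$market, mode = "as_printed")
    oracle <- brute_force_equilibrium(f$market, "institution",
                                      n_grid = 1001, mode = "as_printed")
    expect_lt(abs(sol$q - oracle$q), oracle$solver_meta$step + 1e-12)
    expect_true(is.finite(sol$leader_foc_residual))
    if (isTRUE(sol$interior)) expect_lt(sol$leader_foc_residual, 1e-6)
  }
})

test_that("grid oracle is stable under refinement and solves a known vertex", {
  mp <- fig1_market()
  coarse <- brute_force_equilibrium(mp, "alliance", n_grid = 501)
  fine <- brute_force_equilibrium(mp, "alliance", n_grid = 1001)
  expect_lt(abs(coarse$p - fine$p), coarse$solver_meta$step + 1e-12)
  # the internal multistart maximizer finds the vertex of a concave parabola
  m <- drgpricing:::maximize_scalar(function(x) -(x - 0.3)^2, 0, 1)
  expect_equal(m$x, 0.3, tolerance = 1e-7)
  expect_error(brute_force_equilibrium(mp, "alliance", n_grid = 1001,
                                       opts = solver_options(p_max = 1e6)),
               NA) # wide bounds still bracket the optimum
})

test_that("solver options validate and bounds close the admissible region", {
  expect_error(solver_options(p_max = -1), "p_max")
  mp <- fig1_market()
  b <- drgpricing:::default_bounds(mp, solver_options())
  # at the box corner: price equals marginal cost and demand is exactly zero
  expect_equal(b$p[2], 0.5 * mp$gamma * b$q[2]^2, tolerance = 1e-12)
  q_at_pmax <- follower_quality_response(mp, b$p[2])
  expect_equal(demand(mp, b$p[2], q_at_pmax), 0, tolerance = 1e-10)
})
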