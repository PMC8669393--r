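test_that("full pipeline runs end-to-end with certified first-order conditions", {
  cfg <- drg_preset("fig1")
  pl <- run_pipeline(cfg)
  expect_lt(pl$stage1$leader_foc_residual, 1e-6)
  expect_lt(pl$stage1$follower_foc_residual, 1e-6)
  expect_true(all(pl$stage1$admissible))
  expect_equal(pl$bargain$p_bar <= max(pl$bargain$p1_star, pl$bargain$p2_star) &&
                 pl$bargain$p_bar >= min(pl$bargain$p1_star, pl$bargain$p2_star),
               TRUE)
  expect_gte(pl$copay$lambda_star, 0)
  expect_lte(pl$copay$lambda_star, 1)
  expect_lt(pl$copay$foc_residual, 1e-12)
})

test_that("pipeline is deterministic and propagates stage names on error", {
  cfg <- drg_preset("fig1")
  a <- run_pipeline(cfg)
  b <- run_pipeline(cfg)
  a$provenance$timestamp <- b$provenance$timestamp <- NULL
  expect_identical(a[setdiff(names(a), "provenance")],
                   b[setdiff(names(b), "provenance")])
  # a degenerate bargaining interval collapses to that point and continues
  out <- rubinstein_price(2, 2, cfg$bargaining)
  expect_equal(out$p_bar, 2)
  # errors carry the failing stage's name
  bad <- scenario_config(market_params(0.3, 0.3, 0, 10), # c = 0 -> q1 = 0
                         bargaining = cfg$bargaining,
                         insurance = cfg$insurance)
  expect_error(run_pipeline(bad), "^bargain:")
})

test_that("price sweeps keep inadmissible rows flagged and report directions", {
  sw <- sweep_price_vs_b(drg_preset("fig1"), b_grid = seq(0.1, 0.5, by = 0.1),
                         oracle_points = 3)
  expect_equal(nrow(sw), 5)
  expect_true(all(sw$follower_foc_residual < 1e-8))
  rep <- sweep_report(sw)
  expect_true(rep$direction %in% c("increasing", "decreasing", "flat"))
  expect_identical(rep$oracle_direction, rep$direction)
  # single-point grid: direction undefined
  one <- sweep_price_vs_b(drg_preset("fig1"), b_grid = 0.3, oracle_points = 0)
  expect_identical(sweep_report(one)$direction, "undefined")

  sw2 <- sweep_price_vs_c(drg_preset("fig2"), c_grid = seq(0.2, 1, by = 0.2),
                          oracle_points = 3)
  expect_equal(nrow(sw2), 5)
  expect_true(all(c("flag_Q", "flag_p", "flag_q", "flag_profit") %in% names(sw2)))
  expect_identical(sweep_report(sw2)$oracle_direction,
                   sweep_report(sw2)$direction)
})

test_that("welfare sweep contrasts the two risk-aversion regimes", {
  pp <- copay_params(0.3, 0.15, 0.1, 1, 1, 2)
  ws <- sweep_welfare_vs_lambda(pp)
  expect_lt(ws$R_low, ws$R_crit)
  expect_gt(ws$R_high, ws$R_crit)
  expect_identical(attr(ws$low, "empirical_shape"), "monotone_decreasing")
  expect_identical(attr(ws$high, "empirical_shape"), "U_shaped")
  expect_identical(attr(ws$low, "classified_shape"),
                   attr(ws$low, "empirical_shape"))
  expect_identical(attr(ws$high, "classified_shape"),
                   attr(ws$high, "empirical_shape"))
  # both curves end at the pure risk cost (1/2) R sigma^2
  expect_equal(ws$low$WL[ws$low$lambda == 1], 0.5 * ws$R_low * pp$sigma2)
  expect_equal(ws$high$WL[ws$high$lambda == 1], 0.5 * ws$R_high * pp$sigma2)
  expect_error(sweep_welfare_vs_lambda(copay_params(0.3, 0.4, 0.1, 1, 1, 2)),
               "contrastive")
})

test_that("fixture generator is reproducible and emits only admissible sets", {
  f1 <- generate_fixtures(99, 8)
  f2 <- generate_fixtures(99, 8)
  expect_identical(f1, f2)
  expect_false(identical(f1, generate_fixtures(100, 8)))
  for (f in f1) {
    sol <- solve_stage1(f$market)
    expect_true(all(sol$admissible))
    expect_gt(sol$q, 0)
    expect_true(f$bargaining$theta1 >= 0 && f$bargaining$theta1 < 1)
    expect_true(f$insurance$delta >= 0 && f$insurance$delta <= 0.3)
  }
  # the sampler leaves the global RNG stream untouched
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(generate_fixtures(3, 2)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("scenario configs round-trip through YAML with identical results", {
  cfg <- drg_preset("fig2")
  tf <- tempfile(fileext = ".yaml")
  write_scenario_config(cfg, tf)
  cfg2 <- read_scenario_config(tf)
  expect_equal(unclass(cfg$market), unclass(cfg2$market))
  expect_equal(cfg$sweep, cfg2$sweep)
  expect_identical(drgpricing:::config_hash(cfg),
                   drgpricing:::config_hash(cfg2))
  expect_error(scenario_config(fig1_market(),
                               sweep = list(variable = "zz", lo = 0, hi = 1,
                                            n_points = 5)),
               "sweep variable")
  expect_error(scenario_config(fig1_market(),
                               insurance = list(delta = 0.1, R = 1)),
               "sigma2")
})

test_that("sweep CSV export is bit-identical for identical configs", {
  cfg <- drg_preset("fig1")
  grid <- seq(0.1, 0.4, by = 0.1)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_sweep_csv(sweep_price_vs_b(cfg, grid, oracle_points = 0), f1)
  write_sweep_csv(sweep_price_vs_b(cfg, grid, oracle_points = 0), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(any(grepl("^# config_hash=", readLines(f1))))
})
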