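#' Scenario configuration
#'
#' Bundles everything the pipeline needs: market parameters, bargaining
#' discount factors, insurance-stage parameters, the stage-2 price-response
#' mode, solver options and the seed used by [generate_fixtures()].
#'
#' @param market A [market_params()] object.
#' @param bargaining A [bargaining_params()] object.
#' @param insurance Named list with `delta`, `R`, `sigma2` (see
#'   [copay_params()]; `p_bar` is supplied by the bargaining stage).
#' @param stage2_mode `"as_printed"` (default) or `"derived"`.
#' @param solver A [solver_options()] object.
#' @param sweep Optional list `list(variable, lo, hi, n_points)` with
#'   `variable` one of `"b"`, `"c"`, `"lambda"`, `"R"`, `"theta1"`,
#'   `"theta2"`.
#' @param seed Integer seed for fixture generation.
#' @param preset Optional preset name carried for provenance.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(market,
                            bargaining = bargaining_params(0.5, 0.5),
                            insurance = list(delta = 0.1, R = 1, sigma2 = 1),
                            stage2_mode = c("as_printed", "derived"),
                            solver = solver_options(),
                            sweep = NULL,
                            seed = 1L,
                            preset = NA_character_) {
  stage2_mode <- match.arg(stage2_mode)
  market <- as_market_params(market)
  if (!inherits(bargaining, "bargaining_params")) {
    stop("'bargaining' must be a bargaining_params object", call. = FALSE)
  }
  for (nm in c("delta", "R", "sigma2")) {
    if (is.null(insurance[[nm]])) {
      stop(sprintf("insurance parameters must include '%s'", nm), call. = FALSE)
    }
  }
  if (!is.null(sweep)) {
    ok_vars <- c("b", "c", "lambda", "R", "theta1", "theta2")
    if (!sweep$variable %in% ok_vars) {
      stop("sweep variable must be one of ", paste(ok_vars, collapse = ", "),
           call. = FALSE)
    }
    if (!(sweep$lo < sweep$hi)) stop("sweep requires lo < hi", call. = FALSE)
    if (sweep$n_points < 2) stop("sweep requires n_points >= 2", call. = FALSE)
  }
  structure(list(market = market, bargaining = bargaining,
                 insurance = insurance, stage2_mode = stage2_mode,
                 solver = solver, sweep = sweep, seed = as.integer(seed),
                 preset = preset),
            class = "scenario_config")
}

#' Packaged scenario presets
#'
#' The simulation scenarios shipped with the package. `"fig1"` and `"fig2"`
#' carry the documented market parameterization `a = 0.3`, `gamma = 10`,
#' `c = 0.6`, `b = 0.3` and `F = 0` (the price-sensitivity sweep and the
#' quality-preference sweep respectively). `"fig3"` is the welfare/co-payment
#' contrast scenario: demand `a = 0.3`, `b = 0.15` (price sensitivity below
#' the intercept so that the risk-aversion threshold is positive), incidence
#' `delta = 0.1`, bargained price `p_bar = 2` and price variance
#' `sigma2 = 1`.
#'
#' @param name One of `"fig1"`, `"fig2"`, `"fig3"`.
#' @return A `scenario_config`.
#' @export
drg_preset <- function(name = c("fig1", "fig2", "fig3")) {
  name <- match.arg(name)
  path <- system.file("extdata", "scenarios", paste0(name, ".yaml"),
                      package = "drgpricing")
  if (nzchar(path)) return(read_scenario_config(path))
  # fall back to inline definitions when running from a source checkout
  base_market <- market_params(a = 0.3, b = 0.3, c = 0.6, gamma = 10, F = 0)
  switch(name,
    fig1 = scenario_config(base_market,
                           sweep = list(variable = "b", lo = 0.05, hi = 0.6,
                                        n_points = 23),
                           preset = "fig1"),
    fig2 = scenario_config(base_market,
                           sweep = list(variable = "c", lo = 0.1, hi = 1.2,
                                        n_points = 23),
                           preset = "fig2"),
    fig3 = scenario_config(market_params(a = 0.3, b = 0.15, c = 0.6,
                                         gamma = 10, F = 0),
                           insurance = list(delta = 0.1, R = 1, sigma2 = 1,
                                            p_bar = 2),
                           sweep = list(variable = "lambda", lo = 0, hi = 1,
                                        n_points = 101),
                           preset = "fig3"))
}

#' Read / write a scenario configuration (YAML)
#'
#' The on-disk schema (version 1) mirrors the constructor arguments:
#' top-level keys `market` (a, b, c, gamma, F), `bargaining` (theta1,
#' theta2, convention, first_proposer), `insurance` (delta, R, sigma2,
#' optional p_bar), `stage2_mode`, `sweep`, `seed`, `preset`.
#'
#' @param path File path.
#' @return `read_scenario_config()` returns a `scenario_config`;
#'   `write_scenario_config()` invisibly returns `path`.
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  m <- y$market
  bg <- y$bargaining
  if (is.null(bg)) bg <- list(theta1 = 0.5, theta2 = 0.5)
  ins <- y$insurance
  if (is.null(ins)) ins <- list(delta = 0.1, R = 1, sigma2 = 1)
  scenario_config(
    market = market_params(m$a, m$b, m$c, m$gamma,
                           if (is.null(m$F)) 0 else m$F),
    bargaining = bargaining_params(
      bg$theta1, bg$theta2,
      convention = if (is.null(bg$convention)) "split" else bg$convention,
      first_proposer = if (is.null(bg$first_proposer)) "alliance"
                       else bg$first_proposer),
    insurance = ins,
    stage2_mode = if (is.null(y$stage2_mode)) "as_printed" else y$stage2_mode,
    sweep = y$sweep,
    seed = if (is.null(y$seed)) 1L else y$seed,
    preset = if (is.null(y$preset)) NA_character_ else y$preset)
}

#' @rdname read_scenario_config
#' @param config A `scenario_config`.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  y <- list(
    schema_version = 1L,
    preset = config$preset,
    market = unclass(config$market),
    bargaining = unclass(config$bargaining),
    insurance = config$insurance,
    stage2_mode = config$stage2_mode,
    sweep = config$sweep,
    seed = config$seed)
  yaml::write_yaml(y, path)
  invisible(path)
}

# Deterministic hash of a config for provenance stamping.
config_hash <- function(config) {
  s <- paste(deparse(lapply(unclass(config), unclass)), collapse = "\n")
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf), add = TRUE)
  writeLines(s, tf)
  unname(tools::md5sum(tf))
}

provenance <- function(config) {
  list(preset = config$preset,
       config_hash = config_hash(config),
       package_version = as.character(utils::packageVersion("drgpricing")),
       # timestamp intentionally kept out of serialized outputs so that
       # identical configs produce bit-identical files
       timestamp = format(Sys.time(), tz = "UTC"))
}

#' Run the full three-stage pricing pipeline
#'
#' Executes the chain: stage-1 Stackelberg (alliance leads) -> stage-2
#' Stackelberg (institution leads) -> unit-quality normalization and
#' Rubinstein bargaining -> optimal co-payment ratio. The result is a pure
#' function of the configuration. An `insurance$p_bar` entry in the config,
#' when present, is ignored here: the pipeline always uses the bargained
#' price.
#'
#' @param config A [scenario_config()].
#' @return A list of class `drg_pipeline` with components `stage1`,
#'   `stage2`, `bargain`, `copay`, `config`, `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  run_stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("%s: %s", label, conditionMessage(e)), call. = FALSE)
    })
  }
  s1 <- run_stage("stage1", solve_stage1(config$market, config$solver))
  s2 <- run_stage("stage2", solve_stage2(config$market, config$solver,
                                         mode = config$stage2_mode))
  bar <- run_stage("bargain", {
    p1s <- normalize_unit_price(s1$p, s1$q)
    p2s <- normalize_unit_price(s2$p, s2$q)
    rubinstein_price(p1s, p2s, config$bargaining)
  })
  cp <- run_stage("copay", {
    ins <- config$insurance
    optimal_copay(copay_params(a = config$market$a, b = config$market$b,
                               delta = ins$delta, R = ins$R,
                               sigma2 = ins$sigma2, p_bar = bar$p_bar))
  })
  structure(list(stage1 = s1, stage2 = s2, bargain = bar, copay = cp,
                 config = config, provenance = provenance(config)),
            class = "drg_pipeline")
}

#' @export
print.drg_pipeline <- function(x, ...) {
  cat("DRG pricing pipeline\n")
  cat(sprintf("  stage 1 (alliance leads):    p = %.6g, q = %.6g\n",
              x$stage1$p, x$stage1$q))
  cat(sprintf("  stage 2 (institution leads): p = %.6g, q = %.6g [%s]\n",
              x$stage2$p, x$stage2$q, x$stage2$mode))
  cat(sprintf("  bargained unit price p_bar = %.6g\n", x$bargain$p_bar))
  cat(sprintf("  optimal co-payment lambda* = %.6g (%s)\n",
              x$copay$lambda_star, x$copay$shape))
  invisible(x)
}

direction_label <- function(x, y) {
  if (length(x) < 2 || length(unique(y)) < 2) return("undefined")
  rho <- suppressWarnings(stats::cor(x, y, method = "spearman"))
  if (!is.finite(rho) || rho == 0) return("flat")
  if (rho > 0) "increasing" else "decreasing"
}

monotonicity_report <- function(x, y, expected, oracle_direction = NA) {
  rho <- if (length(x) >= 2 && length(unique(y)) >= 2) {
    suppressWarnings(stats::cor(x, y, method = "spearman"))
  } else NA_real_
  dir <- direction_label(x, y)
  list(direction = dir,
       spearman_rho = rho,
       expected = expected,
       agrees_expected = identical(dir, expected),
       oracle_direction = oracle_direction,
       oracle_agrees = if (is.na(oracle_direction)) NA
                       else identical(dir, oracle_direction))
}

sweep_row <- function(sol, extra) {
  cbind(extra,
        data.frame(p = sol$p, q = sol$q, Q = sol$Q,
                   WF = sol$objectives$WF, Up = sol$objectives$Up,
                   profit = sol$objectives$profit,
                   follower_foc_residual = sol$follower_foc_residual,
                   leader_foc_residual = sol$leader_foc_residual,
                   flag_Q = sol$admissible[["Q"]],
                   flag_p = sol$admissible[["p"]],
                   flag_q = sol$admissible[["q"]],
                   flag_profit = sol$admissible[["profit"]],
                   admissible = all(sol$admissible)))
}

new_sweep_result <- function(df, report, config) {
  structure(df, class = c("sweep_result", "data.frame"),
            report = report, provenance = provenance(config))
}

#' Monotonicity report of a sweep
#'
#' @param x A `sweep_result`.
#' @return The report list (direction, Spearman rho, expected direction,
#'   oracle recomputation and agreement flags).
#' @export
sweep_report <- function(x) attr(x, "report")

#' Stage-1 equilibrium price versus price sensitivity of demand
#'
#' Re-solves the first-round Stackelberg game across a grid of the demand
#' price-sensitivity coefficient `b`, holding the other market parameters at
#' the preset values. Rows whose equilibrium fails an admissibility flag are
#' retained and flagged, never dropped. The monotonicity report records the
#' direction observed on admissible rows, the documented expected direction
#' (`"increasing"`: a positive price/price-sensitivity relationship, the
#' anti-Ramsey claim), and a recomputation of the direction by the
#' brute-force grid oracle on subsampled grid points.
#'
#' @param config A `scenario_config`, default the `"fig1"` preset.
#' @param b_grid Grid of `b` values; defaults to the preset's sweep range.
#' @param oracle_points Number of subsampled grid points at which the oracle
#'   recomputes the equilibrium (0 disables the cross-check).
#' @return A `sweep_result` data.frame (one row per `b`), with the report in
#'   `attr(, "report")`.
#' @export
sweep_price_vs_b <- function(config = drg_preset("fig1"), b_grid = NULL,
                             oracle_points = 5L) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(b_grid)) {
    sw <- config$sweep
    b_grid <- if (!is.null(sw) && identical(sw$variable, "b")) {
      seq(sw$lo, sw$hi, length.out = sw$n_points)
    } else seq(0.05, 0.6, length.out = 23)
  }
  m <- config$market
  rows <- lapply(b_grid, function(b) {
    mp <- market_params(m$a, b, m$c, m$gamma, m$F)
    sol <- solve_stage1(mp, config$solver)
    sweep_row(sol, data.frame(b = b))
  })
  df <- do.call(rbind, rows)
  if (!any(df$admissible)) {
    stop("empty sweep: no admissible stage-1 equilibrium on the b-grid",
         call. = FALSE)
  }
  adm <- df[df$admissible, ]
  oracle_dir <- NA
  if (oracle_points > 0 && nrow(adm) >= 2) {
    idx <- unique(round(seq(1, nrow(adm), length.out = min(oracle_points,
                                                           nrow(adm)))))
    op <- vapply(adm$b[idx], function(b) {
      mp <- market_params(m$a, b, m$c, m$gamma, m$F)
      brute_force_equilibrium(mp, "alliance", opts = config$solver)$p
    }, numeric(1))
    oracle_dir <- direction_label(adm$b[idx], op)
  }
  report <- monotonicity_report(adm$b, adm$p, expected = "increasing",
                                oracle_direction = oracle_dir)
  new_sweep_result(df, report, config)
}

#' Stage-2 equilibrium price versus quality-preference coefficient
#'
#' Re-solves the second-round Stackelberg game (institution leads; price
#' response mode from the config, default `"as_printed"`) across a grid of
#' the patients' quality-preference coefficient `c`. Reporting contract as
#' in [sweep_price_vs_b()]; the direction is assessed on the admissible
#' sub-range only, and the documented expected direction is `"increasing"`
#' (price rises with quality preference).
#'
#' @param config A `scenario_config`, default the `"fig2"` preset.
#' @param c_grid Grid of `c` values; defaults to the preset's sweep range.
#' @param oracle_points Subsample size for the oracle cross-check.
#' @return A `sweep_result`.
#' @export
sweep_price_vs_c <- function(config = drg_preset("fig2"), c_grid = NULL,
                             oracle_points = 5L) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(c_grid)) {
    sw <- config$sweep
    c_grid <- if (!is.null(sw) && identical(sw$variable, "c")) {
      seq(sw$lo, sw$hi, length.out = sw$n_points)
    } else seq(0.1, 1.2, length.out = 23)
  }
  m <- config$market
  mode <- config$stage2_mode
  rows <- lapply(c_grid, function(cc) {
    mp <- market_params(m$a, m$b, cc, m$gamma, m$F)
    sol <- solve_stage2(mp, config$solver, mode = mode)
    sweep_row(sol, data.frame(c = cc))
  })
  df <- do.call(rbind, rows)
  if (!any(df$admissible)) {
    stop("empty sweep: no admissible stage-2 equilibrium on the c-grid",
         call. = FALSE)
  }
  adm <- df[df$admissible, ]
  oracle_dir <- NA
  if (oracle_points > 0 && nrow(adm) >= 2) {
    idx <- unique(round(seq(1, nrow(adm), length.out = min(oracle_points,
                                                           nrow(adm)))))
    op <- vapply(adm$c[idx], function(cc) {
      mp <- market_params(m$a, m$b, cc, m$gamma, m$F)
      brute_force_equilibrium(mp, "institution", mode = mode,
                              opts = config$solver)$p
    }, numeric(1))
    oracle_dir <- direction_label(adm$c[idx], op)
  }
  report <- monotonicity_report(adm$c, adm$p, expected = "increasing",
                                oracle_direction = oracle_dir)
  new_sweep_result(df, report, config)
}

#' Welfare-loss curves across the co-payment ratio, for two risk regimes
#'
#' Produces the loss curve `WL(lambda)` for a low-risk-aversion and a
#' high-risk-aversion patient population around the threshold `R_crit` of
#' [classify_welfare_shape()]: below the threshold the loss decreases
#' monotonically on `[0, 1]` (welfare keeps rising with the co-payment
#' ratio), above it the loss is U-shaped (welfare rises, then falls). When
#' `R_low`/`R_high` are not supplied they are auto-selected as
#' `R_crit/2` and `R_crit + max(1, R_crit)`; this requires `a > b` and
#' `sigma2 > 0` so that the threshold is positive.
#'
#' @param params A [copay_params()] object (its `R` is overridden per
#'   curve).
#' @param R_low,R_high Risk-aversion coefficients for the two curves.
#' @param lambda_grid Grid on `[0, 1]`.
#' @return A list of class `welfare_sweep`: `low` and `high` (data.frames
#'   with `lambda`, `WL`, `R`, classification and empirical shape), plus
#'   `R_low`, `R_high`, `R_crit`.
#' @export
sweep_welfare_vs_lambda <- function(params, R_low = NULL, R_high = NULL,
                                    lambda_grid = seq(0, 1, by = 0.01)) {
  stopifnot(inherits(params, "copay_params"))
  cls <- classify_welfare_shape(params)
  R_crit <- cls$R_crit
  if (is.null(R_low) || is.null(R_high)) {
    if (!is.finite(R_crit) || R_crit <= 0) {
      stop("auto-selection of a contrastive pair requires a > b and sigma2 > 0 (positive R_crit)",
           call. = FALSE)
    }
    if (is.null(R_low)) R_low <- R_crit / 2
    if (is.null(R_high)) R_high <- R_crit + max(1, R_crit)
  }
  one_curve <- function(R) {
    pp <- copay_params(params$a, params$b, params$delta, R, params$sigma2,
                       params$p_bar)
    wl <- welfare_loss(pp, lambda_grid)
    i <- which.min(wl)
    empirical <- if (i == length(lambda_grid)) "monotone_decreasing"
                 else if (i == 1L) "monotone_increasing" else "U_shaped"
    df <- data.frame(lambda = lambda_grid, WL = wl, R = R)
    attr(df, "classified_shape") <- classify_welfare_shape(pp)$shape
    attr(df, "empirical_shape") <- empirical
    df
  }
  structure(list(low = one_curve(R_low), high = one_curve(R_high),
                 R_low = R_low, R_high = R_high, R_crit = R_crit),
            class = "welfare_sweep")
}

#' Seeded generator of admissible random parameter sets
#'
#' Draws full parameter sets (market, bargaining, insurance) from documented
#' ranges -- `a` in `[0.1, 1]`, `b` in `(0, a]`, `c` in `[0.05, 1.5]`,
#' `gamma` in `[1, 20]`, `F` in `[0, 0.02]`, `theta` in `[0, 0.95]`,
#' `delta` in `[0, 0.3]`, `R` in `[0, 5]`, `sigma2` in `[0.1, 4]`,
#' `p_bar` in `[0.5, 4]` -- and keeps only sets whose stage-1 equilibrium
#' passes every admissibility flag with strictly positive quality. The
#' global RNG state is saved and restored, so the sampler is reproducible
#' per seed and side-effect free.
#'
#' @param seed Integer seed.
#' @param n Number of fixtures, `>= 1`.
#' @param max_tries Rejection-sampling cap.
#' @return A list of `n` lists, each with components `market`
#'   ([market_params()]), `bargaining` ([bargaining_params()]) and
#'   `insurance` (delta, R, sigma2, p_bar).
#' @export
generate_fixtures <- function(seed, n, max_tries = 200L * n) {
  stopifnot(n >= 1)
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  out <- vector("list", n)
  k <- 0L
  tries <- 0L
  while (k < n && tries < max_tries) {
    tries <- tries + 1L
    a <- stats::runif(1, 0.1, 1)
    b <- stats::runif(1, 0.01, a)
    cc <- stats::runif(1, 0.05, 1.5)
    gamma <- stats::runif(1, 1, 20)
    F <- stats::runif(1, 0, 0.02)
    mp <- market_params(a, b, cc, gamma, F)
    sol <- tryCatch(solve_stage1(mp), error = function(e) NULL)
    if (is.null(sol) || !all(sol$admissible) || sol$q <= 0) next
    k <- k + 1L
    out[[k]] <- list(
      market = mp,
      bargaining = bargaining_params(stats::runif(1, 0, 0.95),
                                     stats::runif(1, 0, 0.95)),
      insurance = list(delta = stats::runif(1, 0, 0.3),
                       R = stats::runif(1, 0, 5),
                       sigma2 = stats::runif(1, 0.1, 4),
                       p_bar = stats::runif(1, 0.5, 4)))
  }
  if (k < n) {
    stop(sprintf(
      "fixture rejection rate too high: %d admissible sets in %d tries",
      k, tries), call. = FALSE)
  }
  out
}

#' Write a sweep table (or any data.frame) as CSV with provenance header
#'
#' Writes `# key=value` comment lines (preset, config hash, package version
#' -- never a timestamp, so identical configs give bit-identical files)
#' followed by a standard CSV table.
#'
#' @param x A `sweep_result` or plain data.frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_sweep_csv <- function(x, path) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  prov <- attr(x, "provenance")
  if (!is.null(prov)) {
    writeLines(sprintf("# preset=%s", prov$preset), con)
    writeLines(sprintf("# config_hash=%s", prov$config_hash), con)
    writeLines(sprintf("# package_version=%s", prov$package_version), con)
  }
  rep <- attr(x, "report")
  if (!is.null(rep)) {
    writeLines(sprintf("# direction=%s expected=%s oracle=%s",
                       rep$direction, rep$expected,
                       as.character(rep$oracle_direction)), con)
  }
  utils::write.table(as.data.frame(x), con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Plot a sweep result
#'
#' Convenience base-graphics view of a price sweep; the CSV table is the
#' authoritative artifact.
#'
#' @param x A `sweep_result`.
#' @param y Ignored.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sweep_result <- function(x, y, ...) {
  xvar <- setdiff(names(x), c("p", "q", "Q", "WF", "Up", "profit",
                              "follower_foc_residual", "leader_foc_residual",
                              "flag_Q", "flag_p", "flag_q", "flag_profit",
                              "admissible"))[1]
  graphics::plot(x[[xvar]], x$p, type = "b", xlab = xvar,
                 ylab = "equilibrium price",
                 pch = ifelse(x$admissible, 19, 1), ...)
  invisible(x)
}
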