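#' Solver options for the Stackelberg stages
#'
#' @param p_max Upper bound of the leader's price search; `NULL` (default)
#'   derives it from the market parameters, see Details.
#' @param q_max Upper bound of the quality search; `NULL` derives it.
#' @param tol Optimizer tolerance for the bounded 1-D search.
#' @param foc_tol Residual below which a first-order condition counts as
#'   satisfied (numeric leader FOC).
#' @param degeneracy_tol Objective spread below which the stage-2 institution
#'   objective is declared flat (degenerate).
#' @param n_grid Number of grid points used by [brute_force_equilibrium()].
#'
#' @details The default box is the fixed point of "price no larger than the
#' choke price at maximal quality, marginal cost no larger than price":
#' `q_max = (c + sqrt(c^2 + 2*a*b*gamma)) / (b*gamma)` and
#' `p_max = (a + c*q_max)/b`, which satisfy `p_max = (1/2)*gamma*q_max^2`.
#' At `p = p_max` the stage-1 follower response drives demand exactly to
#' zero, so the default box covers the whole admissible stage-1 region.
#'
#' @return A list of class `solver_options`.
#' @export
solver_options <- function(p_max = NULL, q_max = NULL, tol = 1e-10,
                           foc_tol = 1e-6, degeneracy_tol = 1e-9,
                           n_grid = 1001L) {
  if (!is.null(p_max) && (!is.finite(p_max) || p_max <= 0)) {
    stop("'p_max' must be a positive number or NULL", call. = FALSE)
  }
  if (!is.null(q_max) && (!is.finite(q_max) || q_max <= 0)) {
    stop("'q_max' must be a positive number or NULL", call. = FALSE)
  }
  structure(list(p_max = p_max, q_max = q_max, tol = tol, foc_tol = foc_tol,
                 degeneracy_tol = degeneracy_tol,
                 n_grid = as.integer(n_grid)),
            class = "solver_options")
}

# Default search box (see ?solver_options).
default_bounds <- function(params, opts = solver_options()) {
  q_max <- opts$q_max
  if (is.null(q_max)) {
    q_max <- (params$c + sqrt(params$c^2 +
                                2 * params$a * params$b * params$gamma)) /
      (params$b * params$gamma)
  }
  p_max <- opts$p_max
  if (is.null(p_max)) p_max <- (params$a + params$c * q_max) / params$b
  list(p = c(0, p_max), q = c(0, q_max))
}

#' Institution's quality best response (stage-1 follower)
#'
#' For a posted price `p`, the institution's profit
#' `pi = (p - (1/2)*gamma*q^2) * (a - b*p + c*q) - F` is maximized over
#' `q >= 0` at the unique non-negative root of the first-order condition
#' `(3/2)*c*gamma*q^2 + gamma*(a - b*p)*q - c*p = 0`, i.e.
#' `q = (gamma*(b*p - a) + sqrt(gamma^2*(a - b*p)^2 + 6*c^2*gamma*p)) /
#' (3*c*gamma)`. When `c = 0` quality does not enter demand and the response
#' is `q = 0`.
#'
#' @param params A [market_params()] object.
#' @param p Posted treatment price, `p >= 0` (vectorized).
#' @return Profit-maximizing quality level(s).
#' @export
follower_quality_response <- function(params, p) {
  params <- as_market_params(params)
  check_finite_num(p = p)
  if (any(p < 0)) stop("'p' must be non-negative", call. = FALSE)
  if (params$c == 0) return(rep(0, length(p)))
  g <- params$gamma
  disc <- g^2 * (params$a - params$b * p)^2 + 6 * params$c^2 * g * p
  q <- (g * (params$b * p - params$a) + sqrt(disc)) / (3 * params$c * g)
  pmax(q, 0) # root is >= 0 analytically; guard against -0 rounding
}

# Residual of the stage-1 follower FOC (= -dpi/dq).
follower_foc_value <- function(params, p, q) {
  1.5 * params$c * params$gamma * q^2 +
    params$gamma * (params$a - params$b * p) * q - params$c * p
}

#' Alliance's price best response (stage-2 follower)
#'
#' Two readings are provided. `mode = "derived"` solves the alliance's
#' welfare first-order condition `dWF/dp = -b*(p - (1/2)*gamma*q^2) = 0`
#' exactly, giving marginal-cost pricing `p = (1/2)*gamma*q^2`.
#' `mode = "as_printed"` evaluates the literal response
#' `p = (1/2)*c*q^2 + c*q + (a - 1)/b`, kept because it is the reading under
#' which the quality-preference sweep reproduces the documented positive
#' price/preference relationship; it can return negative prices (flagged by
#' callers), which is why it is quarantined behind the mode switch.
#'
#' @param params A [market_params()] object.
#' @param q Quality level chosen by the institution (vectorized).
#' @param mode `"derived"` (exact welfare FOC) or `"as_printed"`.
#' @return Best-response price(s).
#' @export
alliance_price_response <- function(params, q,
                                    mode = c("derived", "as_printed")) {
  params <- as_market_params(params)
  mode <- match.arg(mode)
  check_finite_num(q = q)
  if (any(q < 0)) stop("'q' must be non-negative", call. = FALSE)
  if (mode == "derived") {
    0.5 * params$gamma * q^2
  } else {
    0.5 * params$c * q^2 + params$c * q + (params$a - 1) / params$b
  }
}

# Largest quality with non-negative demand along the as_printed response:
# Q(q) = 1 - (1/2)*b*c*q^2 + c*(1-b)*q, positive root of Q(q) = 0.
as_printed_q_limit <- function(params, fallback) {
  b <- params$b; cc <- params$c
  if (cc <= 0) return(fallback)
  (cc * (1 - b) + sqrt(cc^2 * (1 - b)^2 + 2 * b * cc)) / (b * cc)
}

new_stackelberg_solution <- function(params, leader, mode, p, q,
                                     follower_res, leader_res, bounds,
                                     method, degenerate = FALSE,
                                     interior = NA, extra_meta = list()) {
  Q <- demand(params, p, q)
  prof <- profit(params, p, q)
  Up <- if (Q >= -1e-9) Q^2 / (2 * params$b) else NA_real_
  WF <- if (Q >= -1e-9) .social_welfare_raw(params, p, q) else NA_real_
  structure(list(
    leader = leader,
    mode = mode,
    p = p, q = q, Q = Q,
    objectives = list(WF = WF, Up = Up, profit = prof),
    follower_foc_residual = follower_res,
    leader_foc_residual = leader_res,
    admissible = admissibility_flags(params, p, q),
    degenerate = degenerate,
    interior = interior,
    params = params,
    solver_meta = c(list(bounds = bounds, method = method), extra_meta)
  ), class = "stackelberg_solution")
}

#' @export
print.stackelberg_solution <- function(x, ...) {
  cat(sprintf("Stackelberg equilibrium (leader: %s, mode: %s)\n",
              x$leader, x$mode))
  cat(sprintf("  p = %.6g, q = %.6g, Q = %.6g\n", x$p, x$q, x$Q))
  cat(sprintf("  WF = %.6g, Up = %.6g, profit = %.6g\n",
              x$objectives$WF, x$objectives$Up, x$objectives$profit))
  cat(sprintf("  FOC residuals: leader %.3g, follower %.3g%s%s\n",
              x$leader_foc_residual, x$follower_foc_residual,
              if (isTRUE(x$degenerate)) " [degenerate]" else "",
              if (isFALSE(x$interior)) " [boundary]" else ""))
  bad <- names(x$admissible)[!x$admissible]
  if (length(bad)) cat("  inadmissible flags:", paste(bad, collapse = ", "), "\n")
  invisible(x)
}

#' Solve the first-round Stackelberg game (alliance leads on price)
#'
#' The alliance posts a price `p` to maximize social welfare, anticipating
#' the institution's quality response [follower_quality_response()]. The
#' leader problem `max_p WF(p, q(p))` is solved by bounded multi-start 1-D
#' optimization over `[0, p_max]`, with the search clamped to the admissible
#' region `Q >= 0`. FOC residuals are reported: the leader residual is
#' `|dWF/dp|` by central differences through the follower response, the
#' follower residual is the closed-form quality FOC at the returned point.
#'
#' @param params A [market_params()] object.
#' @param opts A [solver_options()] object.
#' @return A `stackelberg_solution`.
#' @export
solve_stage1 <- function(params, opts = solver_options()) {
  params <- as_market_params(params)
  bounds <- default_bounds(params, opts)
  obj <- function(p) {
    q <- follower_quality_response(params, p)
    # same tolerance as admissibility_flags(): the box corner sits exactly
    # on the zero-demand boundary, where rounding can push Q below 0
    if (params$a - params$b * p + params$c * q < -1e-9) return(-Inf)
    .social_welfare_raw(params, p, q)
  }
  m <- tryCatch(maximize_scalar(obj, bounds$p[1], bounds$p[2], tol = opts$tol),
                error = function(e) {
    stop("no stage-1 equilibrium: demand is negative over the whole price box (flag Q)",
         call. = FALSE)
  })
  p <- m$x
  q <- follower_quality_response(params, p)
  obj_raw <- function(pp) {
    .social_welfare_raw(params, pp, follower_quality_response(params, pp))
  }
  interior <- is_interior(p, bounds$p[1], bounds$p[2])
  leader_res <- abs(numeric_deriv(obj_raw, p, lower = 0))
  follower_res <- abs(follower_foc_value(params, p, q))
  new_stackelberg_solution(params, leader = "alliance", mode = "derived",
                           p = p, q = q,
                           follower_res = follower_res,
                           leader_res = leader_res,
                           bounds = bounds, method = "optimize-multistart",
                           interior = interior)
}

#' Solve the second-round Stackelberg game (institution leads on quality)
#'
#' The institution commits to a quality `q` to maximize profit, anticipating
#' the alliance's price response [alliance_price_response()].
#'
#' With `mode = "derived"` the alliance prices at marginal cost, so the
#' institution's profit is identically `-F` in `q`: the leader objective is
#' structurally flat. The solver detects this (objective spread across a
#' q-grid below `degeneracy_tol`), flags the solution `degenerate`, and
#' returns the smallest quality by the tie-break rule.
#'
#' With `mode = "as_printed"` (the default, used by the quality-preference
#' sweep) the leader problem is a genuine 1-D maximization over
#' `[0, q_hi]`, where `q_hi` is the largest quality with non-negative demand
#' along the printed response. The profit maximum typically sits on that
#' zero-demand boundary, so endpoints are always candidate solutions and
#' boundary solutions are reported as such (`interior = FALSE`).
#'
#' @param params A [market_params()] object.
#' @param opts A [solver_options()] object.
#' @param mode `"as_printed"` (default) or `"derived"`; see
#'   [alliance_price_response()].
#' @return A `stackelberg_solution`.
#' @export
solve_stage2 <- function(params, opts = solver_options(),
                         mode = c("as_printed", "derived")) {
  params <- as_market_params(params)
  mode <- match.arg(mode)
  bounds <- default_bounds(params, opts)

  if (mode == "derived") {
    q_hi <- bounds$q[2]
    grid <- seq(0, q_hi, length.out = 201)
    vals <- profit(params, alliance_price_response(params, grid, "derived"),
                   grid)
    spread <- max(vals) - min(vals)
    degenerate <- spread < opts$degeneracy_tol
    q <- grid[which.max(vals)]
    if (degenerate) q <- 0 # flat objective: tie-break smallest quality
    p <- alliance_price_response(params, q, "derived")
    leader_res <- abs(numeric_deriv(function(qq) {
      profit(params, alliance_price_response(params, qq, "derived"), qq)
    }, q, lower = 0))
    # follower residual: alliance price FOC dWF/dp = -b*(p - mc)
    follower_res <- abs(-params$b * (p - 0.5 * params$gamma * q^2))
    return(new_stackelberg_solution(
      params, leader = "institution", mode = mode, p = p, q = q,
      follower_res = follower_res, leader_res = leader_res,
      bounds = list(p = bounds$p, q = c(0, q_hi)), method = "grid-scan",
      degenerate = degenerate, interior = NA,
      extra_meta = list(objective_spread = spread)))
  }

  q_hi <- as_printed_q_limit(params, fallback = bounds$q[2])
  obj <- function(qq) {
    p <- alliance_price_response(params, qq, "as_printed")
    if (params$a - params$b * p + params$c * qq < -1e-9) return(-Inf)
    profit(params, p, qq)
  }
  m <- tryCatch(maximize_scalar(obj, 0, q_hi, tol = opts$tol),
                error = function(e) {
    stop("no stage-2 equilibrium: demand is negative over the whole quality box (flag Q)",
         call. = FALSE)
  })
  q <- m$x
  p <- alliance_price_response(params, q, "as_printed")
  obj_raw <- function(qq) {
    profit(params, alliance_price_response(params, qq, "as_printed"), qq)
  }
  interior <- is_interior(q, 0, q_hi)
  leader_res <- abs(numeric_deriv(obj_raw, q, lower = 0))
  follower_res <- abs(p - alliance_price_response(params, q, "as_printed"))
  new_stackelberg_solution(params, leader = "institution", mode = mode,
                           p = p, q = q,
                           follower_res = follower_res,
                           leader_res = leader_res,
                           bounds = list(p = bounds$p, q = c(0, q_hi)),
                           method = "optimize-multistart",
                           interior = interior)
}

#' Brute-force grid oracle for the Stackelberg stages
#'
#' Exhaustively evaluates the leader objective on an equally spaced grid,
#' composing the exact follower best response, and returns the grid argmax.
#' This is the independent verification oracle for [solve_stage1()] and
#' [solve_stage2()]: a correct nested solver must agree with the grid argmax
#' to within one grid step.
#'
#' @param params A [market_params()] object.
#' @param leader `"alliance"` (stage-1 layout: grid over price) or
#'   `"institution"` (stage-2 layout: grid over quality).
#' @param n_grid Number of grid points (default from `opts`).
#' @param mode Stage-2 price-response mode, see [solve_stage2()].
#' @param opts A [solver_options()] object.
#' @return A `stackelberg_solution` with `solver_meta$method = "grid-oracle"`
#'   and the grid step recorded in `solver_meta$step`.
#' @export
brute_force_equilibrium <- function(params,
                                    leader = c("alliance", "institution"),
                                    n_grid = NULL,
                                    mode = c("as_printed", "derived"),
                                    opts = solver_options()) {
  params <- as_market_params(params)
  leader <- match.arg(leader)
  mode <- match.arg(mode)
  if (is.null(n_grid)) n_grid <- opts$n_grid
  bounds <- default_bounds(params, opts)

  if (leader == "alliance") {
    lo <- bounds$p[1]; hi <- bounds$p[2]
    grid <- seq(lo, hi, length.out = n_grid)
    qs <- follower_quality_response(params, grid)
    Qs <- demand(params, grid, qs)
    vals <- ifelse(Qs < -1e-9, -Inf, .social_welfare_raw(params, grid, qs))
    if (!any(is.finite(vals))) {
      stop("grid oracle: no admissible price on the grid", call. = FALSE)
    }
    i <- which.max(vals)
    p <- grid[i]; q <- qs[i]
    follower_res <- abs(follower_foc_value(params, p, q))
    leader_res <- NA_real_
    sol_mode <- "derived"
  } else {
    if (mode == "derived") {
      lo <- 0; hi <- bounds$q[2]
    } else {
      lo <- 0; hi <- as_printed_q_limit(params, fallback = bounds$q[2])
    }
    grid <- seq(lo, hi, length.out = n_grid)
    ps <- alliance_price_response(params, grid, mode)
    Qs <- demand(params, ps, grid)
    vals <- ifelse(Qs < -1e-9, -Inf,
                   (ps - 0.5 * params$gamma * grid^2) * Qs - params$F)
    if (!any(is.finite(vals))) {
      stop("grid oracle: no admissible quality on the grid", call. = FALSE)
    }
    i <- which.max(vals)
    q <- grid[i]; p <- ps[i]
    follower_res <- if (mode == "derived") {
      abs(-params$b * (p - 0.5 * params$gamma * q^2))
    } else 0
    leader_res <- NA_real_
    sol_mode <- mode
  }
  step <- (hi - lo) / (n_grid - 1)
  # a strictly interior optimum should be bracketed by the grid; an argmax on
  # the first/last index may indicate a boundary optimum or too coarse a grid
  at_edge <- i == 1L || i == n_grid
  new_stackelberg_solution(params,
                           leader = leader, mode = sol_mode, p = p, q = q,
                           follower_res = follower_res, leader_res = leader_res,
                           bounds = bounds, method = "grid-oracle",
                           interior = !at_edge,
                           extra_meta = list(step = step, n_grid = n_grid,
                                             argmax_at_edge = at_edge))
}
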