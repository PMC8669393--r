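#' Market parameters for a single DRG disease market
#'
#' Bundles the primitives of the linear price/quality market model: demand
#' `Q = a - b*p + c*q` and institution cost `C = F + (1/2)*gamma*q^2*Q`.
#'
#' @param a Demand intercept (number of patients at zero price and quality),
#'   `a >= 0`.
#' @param b Price sensitivity of demand (the "price elasticity of demand"
#'   coefficient of the linear demand function), strictly positive so that
#'   inverse demand exists.
#' @param c Patients' quality-preference coefficient, `c >= 0`. With `c = 0`
#'   demand ignores service quality.
#' @param gamma Quality cost coefficient: the per-patient marginal cost of
#'   serving one case at quality `q` is `(1/2)*gamma*q^2`. Must be positive.
#' @param F Fixed cost of the medical institution, `F >= 0`. Defaults to 0.
#'
#' @return An object of class `market_params` (a validated named list).
#' @examples
#' mp <- market_params(a = 0.3, b = 0.3, c = 0.6, gamma = 10)
#' demand(mp, p = 1, q = 1)
#' @export
market_params <- function(a, b, c, gamma, F = 0) {
  vals <- c(a = a, b = b, c = c, gamma = gamma, F = F)
  if (!all(is.finite(vals))) {
    stop("market parameters must be finite numbers", call. = FALSE)
  }
  if (a < 0 || c < 0) {
    stop("'a' and 'c' must be non-negative", call. = FALSE)
  }
  if (b <= 0) {
    stop("'b' must be strictly positive (degenerate market otherwise)",
         call. = FALSE)
  }
  if (gamma <= 0) stop("'gamma' must be strictly positive", call. = FALSE)
  if (F < 0) stop("'F' must be non-negative", call. = FALSE)
  structure(list(a = a, b = b, c = c, gamma = gamma, F = F),
            class = "market_params")
}

#' @export
print.market_params <- function(x, ...) {
  cat("DRG market parameters:\n")
  cat(sprintf("  a = %g, b = %g, c = %g, gamma = %g, F = %g\n",
              x$a, x$b, x$c, x$gamma, x$F))
  invisible(x)
}

as_market_params <- function(x) {
  if (inherits(x, "market_params")) return(x)
  if (is.list(x)) {
    return(market_params(x$a, x$b, x$c, x$gamma,
                         if (is.null(x$F)) 0 else x$F))
  }
  stop("cannot interpret object as market parameters", call. = FALSE)
}

check_finite_num <- function(...) {
  vals <- c(...)
  if (!all(is.finite(vals))) {
    bad <- names(vals)[!is.finite(vals)]
    stop(sprintf("non-finite input: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Linear demand for medical treatment
#'
#' `Q = a - b*p + c*q`. The raw linear value is returned even when negative;
#' admissibility (`Q >= 0`) is the caller's concern, so that the primitive
#' stays algebraically exact for first-order-condition checks.
#'
#' @param params A [market_params()] object.
#' @param p Treatment price (vectorized).
#' @param q Service-quality level (vectorized).
#' @return Demand `Q` (may be negative).
#' @export
demand <- function(params, p, q) {
  params <- as_market_params(params)
  check_finite_num(p = p, q = q)
  params$a - params$b * p + params$c * q
}

#' Inverse demand (marginal willingness to pay)
#'
#' Solves the demand curve for price: `p = (a + c*q - Q)/b`. This is the
#' integrand of the consumer-surplus integral.
#'
#' @param params A [market_params()] object.
#' @param Qv Quantity demanded.
#' @param q Service-quality level.
#' @return Price at which demand equals `Qv`.
#' @export
inverse_demand <- function(params, Qv, q) {
  params <- as_market_params(params)
  check_finite_num(Qv = Qv, q = q)
  (params$a + params$c * q - Qv) / params$b
}

#' Total cost of the medical institution
#'
#' `C = F + (1/2)*gamma*q^2*Q`: a fixed cost plus a per-case cost quadratic
#' in service quality.
#'
#' @param params A [market_params()] object.
#' @param q Service-quality level, `q >= 0`.
#' @param Qv Number of cases served, `Qv >= 0`.
#' @return Total cost.
#' @export
total_cost <- function(params, q, Qv) {
  params <- as_market_params(params)
  check_finite_num(q = q, Qv = Qv)
  if (any(q < 0) || any(Qv < 0)) {
    stop("'q' and 'Qv' must be non-negative", call. = FALSE)
  }
  params$F + 0.5 * params$gamma * q^2 * Qv
}

#' Profit of the medical institution
#'
#' `pi = p*Q - F - (1/2)*gamma*q^2*Q = (p - (1/2)*gamma*q^2)*Q - F` with
#' `Q = demand(params, p, q)`. The value is computed even at inadmissible
#' points (`Q < 0`) for diagnostic purposes; solvers carry admissibility
#' flags alongside.
#'
#' @inheritParams demand
#' @return Institution profit.
#' @export
profit <- function(params, p, q) {
  params <- as_market_params(params)
  Q <- demand(params, p, q)
  (p - 0.5 * params$gamma * q^2) * Q - params$F
}

# Negative-Q guard shared by the surplus primitives; tiny negative values
# from boundary arithmetic are tolerated.
.check_admissible_Q <- function(Q, tol = 1e-9) {
  if (any(Q < -tol)) {
    stop(sprintf("inadmissible point: demand Q = %.6g < 0", min(Q)),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Patient utility (consumer surplus)
#'
#' The area under inverse demand above the price paid,
#' `Up = Q*(a + c*q)/b - Q^2/(2b) - p*Q`, which for this linear demand equals
#' `Q^2/(2b)`.
#'
#' @inheritParams demand
#' @return Consumer surplus at `(p, q)`; errors if `Q < 0`.
#' @export
patient_utility <- function(params, p, q) {
  params <- as_market_params(params)
  Q <- demand(params, p, q)
  .check_admissible_Q(Q)
  Q * (params$a + params$c * q) / params$b - Q^2 / (2 * params$b) - p * Q
}

#' Total social welfare
#'
#' Consumer surplus plus producer surplus: the price transfer cancels, so
#' `WF = Q*(a + c*q)/b - Q^2/(2b) - F - (1/2)*gamma*q^2*Q`, and
#' `WF = patient_utility + profit` identically.
#'
#' @inheritParams demand
#' @return Social welfare at `(p, q)`; errors if `Q < 0`.
#' @export
social_welfare <- function(params, p, q) {
  params <- as_market_params(params)
  Q <- demand(params, p, q)
  .check_admissible_Q(Q)
  .social_welfare_raw(params, p, q)
}

# Unchecked welfare used internally by solvers that clamp their own search
# region; algebraically identical to social_welfare().
.social_welfare_raw <- function(params, p, q) {
  Q <- params$a - params$b * p + params$c * q
  Q * (params$a + params$c * q) / params$b - Q^2 / (2 * params$b) -
    params$F - 0.5 * params$gamma * q^2 * Q
}

#' Objective values at a price/quality point
#'
#' Evaluates all three stakeholders' objectives at once.
#'
#' @inheritParams demand
#' @return A list with components `WF` (social welfare), `Up` (patient
#'   utility) and `profit`.
#' @export
objective_values <- function(params, p, q) {
  params <- as_market_params(params)
  list(WF = social_welfare(params, p, q),
       Up = patient_utility(params, p, q),
       profit = profit(params, p, q))
}

#' Admissibility flags for a price/quality point
#'
#' A point is admissible when demand, price and quality are non-negative and
#' the institution at least covers its fixed cost (the operational content of
#' the equilibrium-existence condition: `F <= (p - (1/2)*gamma*q^2)*Q`).
#'
#' @inheritParams demand
#' @param tol Numerical slack for the comparisons.
#' @return Named logical vector with elements `Q`, `p`, `q`, `profit`.
#' @export
admissibility_flags <- function(params, p, q, tol = 1e-9) {
  params <- as_market_params(params)
  Q <- demand(params, p, q)
  c(Q = Q >= -tol,
    p = p >= -tol,
    q = q >= -tol,
    profit = profit(params, p, q) >= -tol)
}
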