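#' Insurance-stage parameters
#'
#' Parameters of the co-payment stage, in which the government sets the
#' fraction `lambda` of the bargained price paid out-of-pocket so as to
#' minimize the social-welfare loss of insurance (deadweight loss from moral
#' hazard, expected opportunity cost of public support, and the patients'
#' cost of bearing price risk).
#'
#' @param a,b Demand intercept and price sensitivity (as in
#'   [market_params()]); `b > 0`.
#' @param delta Disease incidence, in `[0, 1]`.
#' @param R Patients' absolute-risk-aversion coefficient, `>= 0`.
#' @param sigma2 Variance of the medical treatment price, `>= 0`.
#' @param p_bar Bargained price from the Rubinstein stage, `> 0`.
#' @return A list of class `copay_params`.
#' @export
copay_params <- function(a, b, delta, R, sigma2, p_bar) {
  check_finite_num(a = a, b = b, delta = delta, R = R, sigma2 = sigma2,
                   p_bar = p_bar)
  if (b <= 0) stop("'b' must be strictly positive", call. = FALSE)
  if (a < 0) stop("'a' must be non-negative", call. = FALSE)
  if (delta < 0 || delta > 1) stop("'delta' must lie in [0, 1]", call. = FALSE)
  if (R < 0) stop("'R' must be non-negative", call. = FALSE)
  if (sigma2 < 0) stop("'sigma2' must be non-negative", call. = FALSE)
  if (p_bar <= 0) stop("'p_bar' must be strictly positive", call. = FALSE)
  structure(list(a = a, b = b, delta = delta, R = R, sigma2 = sigma2,
                 p_bar = p_bar),
            class = "copay_params")
}

#' Insured demand for medical treatment
#'
#' With co-payment ratio `lambda` the patient faces the price `lambda * p`,
#' so demand becomes `D = a - b*lambda*p`.
#'
#' @param a,b Demand parameters.
#' @param lam Co-payment ratio, in `[0, 1]` (vectorized).
#' @param p Medical price.
#' @return Insured demand.
#' @export
copay_demand <- function(a, b, lam, p) {
  check_finite_num(a = a, b = b, lam = lam, p = p)
  if (any(lam < 0 | lam > 1)) {
    stop("co-payment ratio must lie in [0, 1]", call. = FALSE)
  }
  a - b * lam * p
}

#' Social-welfare loss of insurance
#'
#' `WL(lambda) = (1/2)*(1 - lambda)^2*b +
#'   delta*(1 - lambda)*(a - b*lambda)*p_bar + (1/2)*R*lambda^2*sigma2`:
#' the deadweight loss from insurance-induced over-consumption (moral
#' hazard), the government's expected opportunity cost of covering the share
#' `1 - lambda`, and the risk-bearing cost of the out-of-pocket share. WL is
#' quadratic in `lambda` with second derivative `b + 2*b*delta*p_bar +
#' R*sigma2`, hence strictly convex whenever any of those terms is positive.
#'
#' @param params A [copay_params()] object.
#' @param lam Co-payment ratio (vectorized). Values in `[0, 1]` are the
#'   reporting range; any real value is accepted so that first-order
#'   conditions can be checked at the unconstrained minimizer.
#' @return Welfare loss.
#' @export
welfare_loss <- function(params, lam) {
  stopifnot(inherits(params, "copay_params"))
  check_finite_num(lam = lam)
  0.5 * (1 - lam)^2 * params$b +
    params$delta * (1 - lam) * (params$a - params$b * lam) * params$p_bar +
    0.5 * params$R * lam^2 * params$sigma2
}

# Analytic dWL/dlambda.
welfare_loss_deriv <- function(params, lam) {
  -(1 - lam) * params$b -
    params$b * params$delta * params$p_bar * (1 - lam) -
    params$delta * params$p_bar * (params$a - params$b * lam) +
    params$R * lam * params$sigma2
}

#' Optimal co-payment ratio
#'
#' Minimizes [welfare_loss()]: the unconstrained first-order-condition
#' solution is the closed form
#' `lambda* = (b + delta*p_bar*(a + b)) / (b + 2*b*delta*p_bar + R*sigma2)`,
#' unique by strict convexity; the reported operational ratio clamps it to
#' `[0, 1]`. The shape classification and risk-aversion threshold come from
#' [classify_welfare_shape()].
#'
#' @param params A [copay_params()] object.
#' @return A list of class `copay_solution` with `lambda_star_raw`,
#'   `lambda_star` (clamped), `WL_at_opt`, `foc_residual`, `shape`,
#'   `R_crit`, and `demand_at_opt` (flagged, not restricted, when negative).
#' @export
optimal_copay <- function(params) {
  stopifnot(inherits(params, "copay_params"))
  denom <- params$b + 2 * params$b * params$delta * params$p_bar +
    params$R * params$sigma2
  if (denom <= 0) {
    stop("degenerate objective: welfare loss is not strictly convex (zero curvature)",
         call. = FALSE)
  }
  num <- params$b + params$delta * params$p_bar * (params$a + params$b)
  lambda_raw <- num / denom
  lambda_star <- min(max(lambda_raw, 0), 1)
  cls <- classify_welfare_shape(params)
  structure(list(
    lambda_star_raw = lambda_raw,
    lambda_star = lambda_star,
    WL_at_opt = welfare_loss(params, lambda_star),
    foc_residual = abs(welfare_loss_deriv(params, lambda_raw)),
    shape = cls$shape,
    R_crit = cls$R_crit,
    demand_at_opt = params$a - params$b * lambda_star * params$p_bar,
    params = params
  ), class = "copay_solution")
}

#' Welfare-loss shape classification and risk-aversion threshold
#'
#' On `lambda` in `[0, 1]` the convex loss is U-shaped (decreases, then
#' increases) exactly when the unconstrained minimizer lies below 1, and
#' monotonically decreasing otherwise. The threshold risk aversion at which
#' the minimizer hits 1 solves `lambda*_raw = 1`:
#' `R_crit = delta * p_bar * (a - b) / sigma2` (a derived, not printed,
#' expression; requires `sigma2 > 0`). Patients more risk averse than
#' `R_crit` get an interior optimal co-payment ratio.
#'
#' @param params A [copay_params()] object.
#' @return A list with `shape` (`"U_shaped"` or `"monotone_decreasing"`),
#'   `R_crit` (`NA` when `sigma2 = 0`) and `lambda_star_raw`.
#' @export
classify_welfare_shape <- function(params) {
  stopifnot(inherits(params, "copay_params"))
  denom <- params$b + 2 * params$b * params$delta * params$p_bar +
    params$R * params$sigma2
  num <- params$b + params$delta * params$p_bar * (params$a + params$b)
  lambda_raw <- num / denom
  R_crit <- if (params$sigma2 > 0) {
    params$delta * params$p_bar * (params$a - params$b) / params$sigma2
  } else NA_real_
  list(shape = if (lambda_raw < 1) "U_shaped" else "monotone_decreasing",
       R_crit = R_crit,
       lambda_star_raw = lambda_raw)
}

#' Welfare-loss diagnostic grid
#'
#' Evaluates the loss on an equally spaced `lambda` grid, the table behind
#' the welfare/co-payment figures; exportable as CSV via
#' [write_sweep_csv()].
#'
#' @param params A [copay_params()] object.
#' @param n Number of grid points on `[0, 1]`.
#' @return A data.frame with columns `lambda` and `WL`.
#' @export
copay_grid <- function(params, n = 101L) {
  lam <- seq(0, 1, length.out = n)
  data.frame(lambda = lam, WL = welfare_loss(params, lam))
}

#' @export
print.copay_solution <- function(x, ...) {
  cat("Optimal insurance co-payment ratio\n")
  cat(sprintf("  lambda* = %.6g (raw %.6g), WL = %.6g\n",
              x$lambda_star, x$lambda_star_raw, x$WL_at_opt))
  cat(sprintf("  shape on [0,1]: %s; R_crit = %.6g; FOC residual %.3g\n",
              x$shape, x$R_crit, x$foc_residual))
  if (x$demand_at_opt < 0) {
    cat("  note: insured demand at lambda* is negative (flagged)\n")
  }
  invisible(x)
}
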