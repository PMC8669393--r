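#' Bargaining parameters (Rubinstein discount factors)
#'
#' @param theta1 Alliance discount factor, in `[0, 1)`. Per-round patience of
#'   the government-patient alliance: higher means delay is less costly.
#' @param theta2 Institution discount factor, in `[0, 1)`.
#' @param convention `"split"` (default): the standard Rubinstein
#'   subgame-perfect division of the bargaining range. `"literal"`: the
#'   combination `p1* + s * p2*`, retained for traceability; it is not a
#'   convex combination and may leave the bargaining range (warned).
#' @param first_proposer Which party makes the first offer; the first
#'   proposer captures the share `(1 - theta_other)/(1 - theta1*theta2)` of
#'   the bargaining surplus, measured from its preferred end of the range
#'   (the alliance prefers the low price, the institution the high one).
#'
#' @return A list of class `bargaining_params`.
#' @export
bargaining_params <- function(theta1, theta2,
                              convention = c("split", "literal"),
                              first_proposer = c("alliance", "institution")) {
  convention <- match.arg(convention)
  first_proposer <- match.arg(first_proposer)
  check_finite_num(theta1 = theta1, theta2 = theta2)
  if (theta1 < 0 || theta1 >= 1 || theta2 < 0 || theta2 >= 1) {
    stop("discount factors must lie in [0, 1)", call. = FALSE)
  }
  structure(list(theta1 = theta1, theta2 = theta2, convention = convention,
                 first_proposer = first_proposer),
            class = "bargaining_params")
}

#' Unit-quality price normalization
#'
#' Standardizes an equilibrium `(p, q)` to the price level of one unit of
#' quality, `p* = p/q`, the common currency in which the two Stackelberg
#' equilibria enter the bargaining stage.
#'
#' @param p Equilibrium price.
#' @param q Equilibrium quality, strictly positive.
#' @return `p/q`.
#' @export
normalize_unit_price <- function(p, q) {
  check_finite_num(p = p, q = q)
  if (any(q <= 0)) {
    stop("degenerate quality: unit-price normalization requires q > 0",
         call. = FALSE)
  }
  p / q
}

#' Rubinstein alternating-offers bargained price
#'
#' Combines the two unit-quality equilibrium prices into the bargained price
#' over the range `[lo, hi] = [min(p1*, p2*), max(p1*, p2*)]`. The first
#' proposer's equilibrium surplus share is
#' `s = (1 - theta_opponent)/(1 - theta1*theta2)`; under the default
#' convention (`"split"`, alliance proposes first) the price settles at
#' `p_bar = hi - s*(hi - lo)`: a fully impatient opponent (`theta2 = 0`)
#' concedes the proposer's preferred endpoint, and symmetric patience
#' `theta1 = theta2 -> 1` yields the midpoint. The `"literal"` convention
#' computes `p1* + s*p2*` instead and warns when the result leaves the range.
#'
#' @param p1_star Unit-quality price from the stage-1 equilibrium (alliance
#'   led); may also be a `stackelberg_solution`, which is normalized first.
#' @param p2_star Unit-quality price from the stage-2 equilibrium
#'   (institution led); may also be a `stackelberg_solution`.
#' @param params A [bargaining_params()] object.
#' @return A list of class `bargain_outcome` with fields `p1_star`,
#'   `p2_star`, `p_bar`, `alliance_share`, `convention`, `in_range`.
#' @export
rubinstein_price <- function(p1_star, p2_star, params) {
  if (!inherits(params, "bargaining_params")) {
    stop("'params' must be a bargaining_params object", call. = FALSE)
  }
  if (inherits(p1_star, "stackelberg_solution")) {
    p1_star <- normalize_unit_price(p1_star$p, p1_star$q)
  }
  if (inherits(p2_star, "stackelberg_solution")) {
    p2_star <- normalize_unit_price(p2_star$p, p2_star$q)
  }
  check_finite_num(p1_star = p1_star, p2_star = p2_star)
  denom <- 1 - params$theta1 * params$theta2
  if (denom <= 0) stop("theta1*theta2 must be < 1", call. = FALSE)
  alliance_share <- (1 - params$theta2) / denom
  lo <- min(p1_star, p2_star)
  hi <- max(p1_star, p2_star)
  if (params$convention == "split") {
    if (params$first_proposer == "alliance") {
      s <- alliance_share
      p_bar <- hi - s * (hi - lo)
    } else {
      s <- (1 - params$theta1) / denom # institution's share, from the top
      p_bar <- lo + s * (hi - lo)
    }
    in_range <- TRUE
  } else {
    p_bar <- p1_star + alliance_share * p2_star
    in_range <- p_bar >= lo - 1e-12 && p_bar <= hi + 1e-12
    if (!in_range) {
      warning(sprintf(
        "literal bargained price %.6g lies outside the bargaining range [%.6g, %.6g]",
        p_bar, lo, hi), call. = FALSE)
    }
  }
  structure(list(p1_star = p1_star, p2_star = p2_star, p_bar = p_bar,
                 alliance_share = alliance_share,
                 convention = params$convention,
                 first_proposer = params$first_proposer,
                 in_range = in_range),
            class = "bargain_outcome")
}

#' @export
print.bargain_outcome <- function(x, ...) {
  cat("Rubinstein bargained unit-quality price\n")
  cat(sprintf("  p1* = %.6g, p2* = %.6g -> p_bar = %.6g (%s, %s proposes)\n",
              x$p1_star, x$p2_star, x$p_bar, x$convention, x$first_proposer))
  cat(sprintf("  alliance surplus share = %.6g%s\n", x$alliance_share,
              if (!x$in_range) " [outside bargaining range]" else ""))
  invisible(x)
}
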