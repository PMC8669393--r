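# Internal 1-D optimization helpers.
#
# stats::optimize() assumes a unimodal objective; the leader objectives here
# can be bimodal (an interior profit peak competing with the zero-demand
# boundary) or have their maximum exactly on the boundary of the admissible
# region, where golden-section search never lands. The maximizer therefore
# scans a coarse grid, locally refines every scanned local maximum with
# stats::optimize(), and always keeps the interval endpoints as candidates.
# Tie-break: larger objective, then smaller argument.

maximize_scalar <- function(f, lower, upper, tol = 1e-10, n_scan = 201L) {
  if (!is.finite(lower) || !is.finite(upper) || upper < lower) {
    stop("invalid search interval", call. = FALSE)
  }
  if (upper == lower) {
    return(list(x = lower, value = f(lower)))
  }
  xs <- seq(lower, upper, length.out = n_scan)
  vals <- vapply(xs, f, numeric(1))
  finite <- is.finite(vals)
  if (!any(finite)) {
    stop("objective is not finite anywhere on the search interval",
         call. = FALSE)
  }
  work <- ifelse(finite, vals, -.Machine$double.xmax)
  peaks <- unique(c(which.max(work),
                    which(diff(sign(diff(work))) == -2) + 1L))
  cands <- c(lower, upper)
  for (j in peaks) {
    lo <- xs[max(j - 1L, 1L)]
    hi <- xs[min(j + 1L, n_scan)]
    if (hi > lo) {
      o <- stats::optimize(f, interval = c(lo, hi), maximum = TRUE, tol = tol)
      cands <- c(cands, o$maximum)
    }
    cands <- c(cands, xs[j])
  }
  cvals <- vapply(cands, f, numeric(1))
  cfin <- is.finite(cvals)
  best <- max(cvals[cfin])
  near <- cfin & cvals >= best - 1e-12 * (abs(best) + 1)
  x <- min(cands[near])
  list(x = x, value = f(x))
}

# Central-difference derivative; falls back to a one-sided difference when a
# bound is within h of x (the residual is then reported for a boundary point).
numeric_deriv <- function(f, x, h = NULL, lower = -Inf, upper = Inf) {
  if (is.null(h)) h <- 1e-6 * max(1, abs(x))
  lo <- max(x - h, lower)
  hi <- min(x + h, upper)
  if (hi <= lo) return(0)
  (f(hi) - f(lo)) / (hi - lo)
}

is_interior <- function(x, lower, upper, rel = 1e-6) {
  span <- upper - lower
  x > lower + rel * span && x < upper - rel * span
}
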