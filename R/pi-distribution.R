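## The MaxEnt intraspecific spatial occupancy distribution Pi(n | A, n0, A0):
## the probability that n of a species' n0 individuals fall in a quadrat of
## area A inside a community of area A0. The MaxEnt solution is a truncated
## geometric pmf on n = 0..n0,
##
##   Pi(n) = x^n / Z,   Z = sum_{m=0}^{n0} x^m,   x = exp(-lambda),
##
## with lambda the Lagrange multiplier enforcing the mean constraint
## E[n] = n0 * A/A0. All root finding happens in lambda >= 0 (downscaling
## only: A/A0 <= 1/2 implies lambda >= 0), where the mean
##
##   m(lambda) = 1/expm1(lambda) - (n0+1)/expm1((n0+1) lambda)
##
## is strictly decreasing from n0/2 at lambda = 0, so a safeguarded bisection
## always converges. Near lambda = 0 the two expm1 terms cancel
## catastrophically; a series expansion takes over there.

## Mean of the truncated geometric pmf as a function of lambda (vectorised
## over n0 and lambda jointly). Stable for lambda in [0, Inf).
pi_mean_lambda <- function(lambda, n0) {
  u <- n0 + 1
  z <- u * lambda
  out <- numeric(length(z))
  small <- z < 1e-4
  if (any(small)) {
    ## 1/expm1(z) = 1/z - 1/2 + z/12 - z^3/720 + O(z^5), applied to both terms
    l <- lambda[small]
    us <- u[small]
    out[small] <- (us - 1) / 2 - (us^2 - 1) * l / 12 + (us^4 - 1) * l^3 / 720
  }
  if (any(!small)) {
    l <- lambda[!small]
    ub <- u[!small]
    ## expm1 overflows to Inf for large arguments; u/Inf = 0 is the right limit
    out[!small] <- 1 / expm1(l) - ub / expm1(ub * l)
  }
  out
}

## Vectorised solver for the multiplier: n0 may be a vector, area_fraction is
## a scalar. Returns x = exp(-lambda). Used heavily by the theoretical SAR
## variants (one call covers n0 = 1..N0 at a given depth).
solve_pi_multiplier_vec <- function(n0, area_fraction) {
  stopifnot(length(area_fraction) == 1L)
  if (!is.finite(area_fraction) || area_fraction <= 0 || area_fraction > 0.5) {
    stop("area_fraction must lie in (0, 1/2]; upscaling (A/A0 > 1/2) is not supported",
         call. = FALSE)
  }
  if (length(n0) == 0L) return(numeric(0))
  if (any(!is.finite(n0) | n0 < 1 | n0 != floor(n0))) {
    stop("n0 must be a positive integer", call. = FALSE)
  }
  x <- rep(1, length(n0))
  if (area_fraction == 0.5) return(x)  # lambda = 0 exactly (uniform limit)
  target <- n0 * area_fraction
  lo <- numeric(length(n0))
  ## m(lambda) <= 1/expm1(lambda), so lambda_hi = log1p(1/target) brackets
  hi <- log1p(1 / target)
  for (iter in 1:90) {
    mid <- (lo + hi) / 2
    high <- pi_mean_lambda(mid, n0) > target
    lo[high] <- mid[high]
    hi[!high] <- mid[!high]
  }
  exp(-(lo + hi) / 2)
}

#' Lagrange multiplier of the spatial occupancy distribution
#'
#' Solves for `x = exp(-lambda)` such that the truncated geometric pmf
#' `Pi(n) = x^n / Z` on `n = 0..n0` has mean `n0 * area_fraction`. This is the
#' single unknown of the MaxEnt spatial occupancy problem: the constraint is
#' the expected number of individuals in a quadrat of relative area
#' `area_fraction = A/A0`.
#'
#' Only downscaling is supported (`area_fraction <= 1/2`, hence `x <= 1`);
#' at exactly half area the solution is the uniform limit `x = 1`.
#'
#' @param n0 species abundance at the community scale; positive integer.
#' @param area_fraction relative quadrat area `A/A0` in `(0, 1/2]`.
#' @return the multiplier `x = exp(-lambda)`, a positive scalar `<= 1`.
#' @examples
#' solve_pi_multiplier(5, 0.5)    # 1: all arrangements equally likely
#' solve_pi_multiplier(1, 0.25)   # 1/3
#' @export
solve_pi_multiplier <- function(n0, area_fraction) {
  stopifnot(length(n0) == 1L)
  solve_pi_multiplier_vec(n0, area_fraction)
}

#' Spatial occupancy pmf, non-recursive (direct) form
#'
#' Constructs `Pi(n | A, n0, A0)` at an arbitrary relative area by solving the
#' mean constraint directly from the community-scale state. Works at any
#' `area_fraction` in `(0, 1/2]`, not only powers of 1/2.
#'
#' @inheritParams solve_pi_multiplier
#' @return an object of class `occupancy_pmf`: list with `probs` (length
#'   `n0 + 1`, indexed by `n = 0..n0`), `n0`, `area_fraction`, `multiplier`,
#'   and `depth` (`NA` for the direct form).
#' @examples
#' occupancy_pmf_direct(4, 0.5)$probs   # uniform 1/5
#' @export
occupancy_pmf_direct <- function(n0, area_fraction) {
  x <- solve_pi_multiplier(n0, area_fraction)
  if (x == 1) {
    probs <- rep(1 / (n0 + 1), n0 + 1)
  } else {
    w <- exp(-(0:n0) * (-log(x)))
    probs <- w / sum(w)
  }
  structure(
    list(probs = probs, n0 = n0, area_fraction = area_fraction,
         multiplier = x, depth = NA_integer_),
    class = "occupancy_pmf"
  )
}

#' Spatial occupancy pmf, recursive (HEAP) form
#'
#' Constructs `Pi(n | A0/2^depth, n0, A0)` by repeated bisection. One halving
#' gives the uniform distribution `1/(n0 + 1)` (every split of `n0`
#' individuals between two equal halves is equally likely); each further
#' halving applies
#' `Pi_i(n) = sum_{q >= n} Pi_{i-1}(q) / (q + 1)`,
#' which is the occupancy law of the HEAP (Hypothesis of Equal Allocation
#' Probabilities) model.
#'
#' @param n0 species abundance at the community scale; positive integer.
#' @param depth number of successive bisections; integer `>= 1`.
#' @return an `occupancy_pmf` with `area_fraction = 2^-depth` and
#'   `multiplier = NA` (no single geometric multiplier exists for depth > 1).
#' @examples
#' occupancy_pmf_recursive(2, 2)$probs  # 11/18, 5/18, 2/18
#' @export
occupancy_pmf_recursive <- function(n0, depth) {
  stopifnot(length(n0) == 1L, length(depth) == 1L)
  if (!is.finite(n0) || n0 < 1 || n0 != floor(n0)) {
    stop("n0 must be a positive integer", call. = FALSE)
  }
  if (!is.finite(depth) || depth < 1 || depth != floor(depth)) {
    stop("depth must be an integer >= 1", call. = FALSE)
  }
  probs <- rep(1 / (n0 + 1), n0 + 1)
  inv <- 1 / (0:n0 + 1)
  if (depth > 1) {
    for (i in 2:depth) {
      probs <- rev(cumsum(rev(probs * inv)))
    }
  }
  structure(
    list(probs = probs, n0 = n0, area_fraction = 2^-depth,
         multiplier = NA_real_, depth = as.integer(depth)),
    class = "occupancy_pmf"
  )
}

#' Vacancy probability under the direct occupancy model
#'
#' `Pi(0 | A, n0, A0) = 1/Z`, the probability that a species with community
#' abundance `n0` is absent from a quadrat of relative area `area_fraction`.
#' Closed form `(1 - x)/(1 - x^(n0+1))` for `x < 1`, `1/(n0 + 1)` at the
#' half-area limit `x = 1`. Expected richness is the sum of per-species
#' occupancies `1 - Pi(0)`, so this is the workhorse of all SAR variants.
#'
#' @param n0 vector of positive integer abundances.
#' @param area_fraction relative quadrat area `A/A0` in `(0, 1/2]` (scalar).
#' @return vector of vacancy probabilities, same length as `n0`.
#' @examples
#' vacancy_direct(4, 0.5)              # 0.2
#' 1 - vacancy_direct(c(1, 10), 0.25)  # per-species occupancy probabilities
#' @export
vacancy_direct <- function(n0, area_fraction) {
  x <- solve_pi_multiplier_vec(n0, area_fraction)
  u <- n0 + 1
  lam <- -log(x)
  v <- numeric(length(x))
  at1 <- lam == 0
  v[at1] <- 1 / u[at1]
  ## (1-x)/(1-x^u) = expm1(-lam)/expm1(-u*lam), stable for all lam > 0
  v[!at1] <- expm1(-lam[!at1]) / expm1(-u[!at1] * lam[!at1])
  v
}

#' @export
print.occupancy_pmf <- function(x, ...) {
  form <- if (is.na(x$depth)) "direct (non-recursive)" else
    sprintf("recursive, depth %d", x$depth)
  cat(sprintf("Spatial occupancy pmf Pi(n | A/A0 = %g, n0 = %d) [%s]\n",
              x$area_fraction, x$n0, form))
  cat(sprintf("  vacancy Pi(0) = %.6g; mean = %.6g\n",
              x$probs[1], sum((0:x$n0) * x$probs)))
  invisible(x)
}
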