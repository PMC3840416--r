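## The METE species-abundance distribution: a log-series truncated at N0,
##   Phi(n | N0, S0) = (x^n / n) / Z,  n = 1..floor(N0),
## with x = exp(-beta) solved so that the mean abundance equals N0/S0 (the
## "individuals per species" constraint). Fractional S0 and N0 are accepted:
## subplot averaging and the recursive SAR feedback both produce them; the
## support uses the integer part of N0 while the constraint uses the real
## ratio.

## Mean of the truncated log-series at multiplier x, support 1..M.
## Computed in log space so x^n underflows gracefully for large n.
sad_mean <- function(x, M) {
  if (x <= 0) return(1)
  n <- seq_len(M)
  lw <- n * log(x) - log(n)       # log(x^n / n)
  lw <- lw - max(lw)
  w <- exp(lw)
  sum(w * n) / sum(w)
}

#' Truncated log-series species-abundance distribution
#'
#' Solves the METE SAD: `Phi(n)` proportional to `sad_x^n / n` on
#' `n = 1..floor(N0)`, with `sad_x` chosen so the mean abundance per species
#' equals `N0/S0`. The multiplier is found by bracketed bisection on
#' `sad_x` in `(0, Inf)`; the mean is strictly increasing in `sad_x`, from 1
#' (all singletons) through `M / H_M` at `sad_x = 1` (`H_M` the harmonic
#' number) towards `M` as `sad_x` grows. Values above 1 (a negative
#' log-series exponent) are legitimate: they arise whenever
#' `N0/S0 > N0/log(N0)`, i.e. species-poor but individual-rich communities
#' such as species-poor woodlands or dense grasslands. A required mean at or
#' above the truncation point `M` is unreachable and rejected.
#'
#' @param S0 community species richness; positive real (fractional values
#'   from subplot averaging or recursive feedback are accepted).
#' @param N0 community abundance; positive real, `N0 >= S0`.
#' @param truncate_tail if `TRUE`, drop the abundance tail once cumulative
#'   probability exceeds `1 - 1e-9` and renormalise (a speed knob for very
#'   large `N0`); the default computes the exact support `1..floor(N0)`.
#' @return an object of class `mete_sad`: list with `probs` (over
#'   `n = 1..floor(N0)`), `sad_x` (`= exp(-beta)`; 0 in the degenerate
#'   all-singleton limit `N0/S0 = 1`), `S0`, `N0`.
#' @examples
#' solve_sad(10, 10)$probs[1]  # 1: every species a singleton
#' solve_sad(4, 16)$sad_x      # about 0.94
#' @export
solve_sad <- function(S0, N0, truncate_tail = FALSE) {
  stopifnot(length(S0) == 1L, length(N0) == 1L)
  if (!is.finite(S0) || !is.finite(N0) || S0 < 1) {
    stop("S0 and N0 must be finite with S0 >= 1", call. = FALSE)
  }
  if (N0 < S0) stop("N0 must be >= S0", call. = FALSE)
  M <- floor(N0)
  target <- N0 / S0
  n <- seq_len(M)
  if (target <= 1) {
    ## N0/S0 = 1: mean constraint forces every species to a singleton
    probs <- c(1, rep(0, M - 1L))
    return(structure(list(probs = probs, sad_x = 0, S0 = S0, N0 = N0),
                     class = "mete_sad"))
  }
  if (target >= M) {
    stop(sprintf(
      "N0/S0 = %.6g is unreachable for a log-series truncated at %d (mean < %d for any multiplier)",
      target, M, M), call. = FALSE)
  }
  hi <- 1
  while (sad_mean(hi, M) < target) {
    hi <- hi * 2
    if (hi > 1e9) {
      stop("SAD multiplier search failed to bracket the mean constraint",
           call. = FALSE)
    }
  }
  lo <- if (hi > 1) hi / 2 else 0
  for (iter in 1:90) {
    mid <- (lo + hi) / 2
    if (sad_mean(mid, M) < target) lo <- mid else hi <- mid
  }
  x <- (lo + hi) / 2
  lw <- n * log(x) - log(n)
  lw <- lw - max(lw)
  w <- exp(lw)
  probs <- w / sum(w)
  if (truncate_tail) {
    keep <- which(cumsum(probs) < 1 - 1e-9)
    k <- min(length(keep) + 1L, M)
    probs <- probs[seq_len(k)]
    probs <- probs / sum(probs)
  }
  structure(list(probs = probs, sad_x = x, S0 = S0, N0 = N0),
            class = "mete_sad")
}

#' @export
print.mete_sad <- function(x, ...) {
  cat(sprintf("Truncated log-series SAD: S0 = %g, N0 = %g, mean n = %g\n",
              x$S0, x$N0, x$N0 / x$S0))
  cat(sprintf("  multiplier sad_x = %.8g; support 1..%d\n",
              x$sad_x, length(x$probs)))
  invisible(x)
}
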