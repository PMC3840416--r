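## The four METE SAR variants: {recursive, non-recursive} downscaling
## crossed with {theoretical, observed} SAD. Expected richness at relative
## area a is the sum over species of occupancy probabilities 1 - Pi(0).
##
## One convention deserves note: richness "at A0/2" always uses the
## half-area vacancy 1/(n0 + 1) (the lambda = 0 limit), so all four variants
## coincide exactly at one bisection; the recursive forms then descend one
## halving at a time from there.

#' Construct a species-area curve
#'
#' A `sar_curve` is a data frame with one row per bisection depth and
#' columns `depth`, `area_fraction` (`= 2^-depth`), `richness` and
#' `abundance` (mean individuals per quadrat; `NA` when unknown), carrying
#' `downscaling` and `sad_source` attributes identifying its provenance.
#'
#' @param depth integer vector of bisection depths.
#' @param richness mean richness per quadrat at each depth.
#' @param abundance mean abundance per quadrat at each depth, or `NULL`.
#' @param downscaling,sad_source provenance labels.
#' @return a `sar_curve`.
#' @export
sar_curve <- function(depth, richness, abundance = NULL,
                      downscaling = NA_character_, sad_source = NA_character_) {
  df <- data.frame(
    depth = as.integer(depth),
    area_fraction = 2^-as.integer(depth),
    richness = richness,
    abundance = if (is.null(abundance)) NA_real_ else abundance
  )
  structure(df, class = c("sar_curve", "data.frame"),
            downscaling = downscaling, sad_source = sad_source)
}

validate_abundances <- function(abundances) {
  if (length(abundances) == 0L) {
    stop("abundance vector must contain at least one species", call. = FALSE)
  }
  if (any(!is.finite(abundances) | abundances < 1 |
            abundances != floor(abundances))) {
    stop("abundances must be positive integers", call. = FALSE)
  }
  invisible(abundances)
}

check_max_depth <- function(max_depth) {
  if (length(max_depth) != 1L || !is.finite(max_depth) || max_depth < 1 ||
        max_depth != floor(max_depth)) {
    stop("max_depth must be an integer >= 1", call. = FALSE)
  }
  as.integer(max_depth)
}

#' Default number of bisections for a community of N0 individuals
#'
#' `floor(log2(N0 / 4))` capped at 14, so the finest quadrats hold about four
#' individuals on average. The theory places no intrinsic limit on depth;
#' this is a practical default for nested-grid comparisons.
#'
#' @param N0 community abundance.
#' @return integer depth `>= 1`.
#' @export
default_max_depth <- function(N0) {
  max(1L, min(14L, as.integer(floor(log2(N0 / 4)))))
}

#' SAR variants
#'
#' The four Table-style METE richness predictions at every bisection depth
#' `i = 0..max_depth` (quadrat area `A0/2^i`).
#'
#' \describe{
#' \item{`sar_nonrecursive_observed`}{richness at depth `i` is
#'   `sum_j (1 - Pi(0 | 2^-i, n0_j))` with the direct occupancy solution per
#'   species, computed independently at each depth from the community-scale
#'   abundances.}
#' \item{`sar_recursive_observed`}{the same sum, but with the vacancy taken
#'   from the recursive (HEAP) occupancy distribution; species identities and
#'   community-scale abundances are retained at all depths.}
#' \item{`sar_nonrecursive_theoretical`}{`S0 * sum_n (1 - Pi(0 | 2^-i, n)) *
#'   Phi(n | N0, S0)` with the log-series SAD solved once at the community
#'   scale.}
#' \item{`sar_recursive_theoretical`}{iterative halving: from `(S_i, N_i)`
#'   compute `S_{i+1} = S_i * sum_n (1 - 1/(n+1)) Phi(n | N_i, S_i)` using
#'   the half-area vacancy, set `N_{i+1} = N_i / 2`, re-solve the SAD at the
#'   new state, repeat. The curve is truncated (with a message) if the
#'   predicted state degenerates (`S < 1` or `N < S`).}
#' }
#'
#' @param abundances vector of positive integer species abundances at the
#'   community scale (the observed SAD).
#' @param state list or named vector with `S0` and `N0` (positive reals,
#'   `N0 >= S0`); `A0` never enters because only area ratios matter.
#' @param max_depth number of bisections; integer `>= 1`.
#' @return a `sar_curve` data frame with columns `depth`, `area_fraction`,
#'   `richness`, `abundance` (mean individuals per quadrat, `N0 * 2^-depth`,
#'   or the recursively updated `N` for the recursive-theoretical variant).
#' @examples
#' sar_nonrecursive_observed(c(1, 10), max_depth = 2)
#' sar_recursive_theoretical(list(S0 = 4, N0 = 16), max_depth = 3)
#' @name sar_variants
NULL

#' @rdname sar_variants
#' @export
sar_nonrecursive_observed <- function(abundances, max_depth) {
  validate_abundances(abundances)
  max_depth <- check_max_depth(max_depth)
  S0 <- length(abundances)
  N0 <- sum(abundances)
  tab <- table(abundances)
  uniq <- as.integer(names(tab))
  cnt <- as.numeric(tab)
  rich <- c(S0, vapply(seq_len(max_depth), function(i) {
    sum(cnt * (1 - vacancy_direct(uniq, 2^-i)))
  }, numeric(1)))
  sar_curve(0:max_depth, rich, N0 * 2^-(0:max_depth),
            downscaling = "nonrecursive", sad_source = "observed")
}

## Vacancy of the recursive occupancy pmf at depths 1..max_depth for one n0.
recursive_vacancy_profile <- function(n0, max_depth) {
  probs <- rep(1 / (n0 + 1), n0 + 1)
  inv <- 1 / (0:n0 + 1)
  v <- numeric(max_depth)
  v[1] <- probs[1]
  if (max_depth > 1) {
    for (i in 2:max_depth) {
      probs <- rev(cumsum(rev(probs * inv)))
      v[i] <- probs[1]
    }
  }
  v
}

#' @rdname sar_variants
#' @export
sar_recursive_observed <- function(abundances, max_depth) {
  validate_abundances(abundances)
  max_depth <- check_max_depth(max_depth)
  S0 <- length(abundances)
  N0 <- sum(abundances)
  tab <- table(abundances)
  uniq <- as.integer(names(tab))
  cnt <- as.numeric(tab)
  vac <- vapply(uniq, recursive_vacancy_profile, numeric(max_depth),
                max_depth = max_depth)
  vac <- matrix(vac, nrow = max_depth)       # depths x unique abundances
  rich <- c(S0, as.numeric((1 - vac) %*% cnt))
  sar_curve(0:max_depth, rich, N0 * 2^-(0:max_depth),
            downscaling = "recursive", sad_source = "observed")
}

check_state <- function(state) {
  state <- as.list(state)
  if (is.null(state$S0) || is.null(state$N0)) {
    stop("state must provide S0 and N0", call. = FALSE)
  }
  S0 <- as.numeric(state$S0)
  N0 <- as.numeric(state$N0)
  if (!is.finite(S0) || !is.finite(N0) || S0 < 1 || N0 < S0) {
    stop("state requires finite N0 >= S0 >= 1", call. = FALSE)
  }
  list(S0 = S0, N0 = N0)
}

#' @rdname sar_variants
#' @export
sar_nonrecursive_theoretical <- function(state, max_depth) {
  st <- check_state(state)
  max_depth <- check_max_depth(max_depth)
  sad <- solve_sad(st$S0, st$N0)
  n <- seq_along(sad$probs)
  rich <- c(st$S0, vapply(seq_len(max_depth), function(i) {
    st$S0 * sum((1 - vacancy_direct(n, 2^-i)) * sad$probs)
  }, numeric(1)))
  sar_curve(0:max_depth, rich, st$N0 * 2^-(0:max_depth),
            downscaling = "nonrecursive", sad_source = "theoretical")
}

#' @rdname sar_variants
#' @export
sar_recursive_theoretical <- function(state, max_depth) {
  st <- check_state(state)
  max_depth <- check_max_depth(max_depth)
  S <- st$S0
  N <- st$N0
  depth <- 0L
  rich <- S
  abund <- N
  while (depth < max_depth) {
    sad <- tryCatch(solve_sad(S, N), error = function(e) NULL)
    if (is.null(sad)) {
      message(sprintf(
        "recursive-theoretical SAR truncated at depth %d: SAD infeasible at predicted state (S = %.4g, N = %.4g)",
        depth, S, N))
      break
    }
    n <- seq_along(sad$probs)
    S_next <- S * sum((1 - 1 / (n + 1)) * sad$probs)  # half-area vacancy
    N_next <- N / 2
    if (S_next < 1 || N_next < S_next) {
      message(sprintf(
        "recursive-theoretical SAR truncated at depth %d: predicted state (S = %.4g, N = %.4g) degenerates",
        depth, S_next, N_next))
      break
    }
    S <- S_next
    N <- N_next
    depth <- depth + 1L
    rich <- c(rich, S)
    abund <- c(abund, N)
  }
  sar_curve(0:depth, rich, abund,
            downscaling = "recursive", sad_source = "theoretical")
}

#' Predict all METE SAR variants on a shared depth grid
#'
#' @param state list with `S0`, `N0`; may be omitted (`NULL`) when
#'   `abundances` is given, in which case `S0 = length(abundances)` and
#'   `N0 = sum(abundances)`.
#' @param abundances observed abundance vector, required for the two
#'   observed-SAD variants; `NULL` restricts output to the theoretical pair.
#' @param max_depth number of bisections shared by all curves.
#' @return named list of `sar_curve`s, keys
#'   `"nonrecursive_theoretical"`, `"recursive_theoretical"` and (when
#'   abundances are supplied) `"nonrecursive_observed"`,
#'   `"recursive_observed"`.
#' @examples
#' predict_all_variants(abundances = c(1, 10), max_depth = 1)
#' @export
predict_all_variants <- function(state = NULL, abundances = NULL,
                                 max_depth = NULL) {
  if (is.null(state) && is.null(abundances)) {
    stop("supply state variables, an abundance vector, or both", call. = FALSE)
  }
  if (!is.null(abundances)) validate_abundances(abundances)
  if (is.null(state)) {
    state <- list(S0 = length(abundances), N0 = sum(abundances))
  } else {
    state <- check_state(state)
    if (!is.null(abundances)) {
      if (abs(state$S0 - length(abundances)) > 1e-8 ||
            abs(state$N0 - sum(abundances)) > 1e-8) {
        stop(sprintf(
          "state (S0 = %g, N0 = %g) is inconsistent with the abundance vector (S = %d, N = %d)",
          state$S0, state$N0, length(abundances), sum(abundances)),
          call. = FALSE)
      }
    }
  }
  if (is.null(max_depth)) max_depth <- default_max_depth(state$N0)
  out <- list(
    nonrecursive_theoretical = sar_nonrecursive_theoretical(state, max_depth),
    recursive_theoretical = sar_recursive_theoretical(state, max_depth)
  )
  if (!is.null(abundances)) {
    out$nonrecursive_observed <- sar_nonrecursive_observed(abundances, max_depth)
    out$recursive_observed <- sar_recursive_observed(abundances, max_depth)
  }
  out
}

#' Serialise SAR curves to a delimited table
#'
#' Writes (or returns) a long-format table with columns `depth`,
#' `area_fraction`, `richness`, `abundance`, `variant_downscaling`,
#' `variant_sad`, rows ordered by variant label then depth.
#'
#' @param curves a single `sar_curve` or a (possibly named) list of them.
#' @param path output file; `NULL` returns the data frame without writing.
#' @param sep field separator.
#' @return the assembled data frame, invisibly when written to `path`.
#' @export
write_sar_table <- function(curves, path = NULL, sep = ",") {
  if (inherits(curves, "sar_curve")) curves <- list(curves)
  rows <- lapply(curves, function(cv) {
    df <- as.data.frame(cv)
    df$variant_downscaling <- attr(cv, "downscaling")
    df$variant_sad <- attr(cv, "sad_source")
    df
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$variant_downscaling, out$variant_sad, out$depth), ,
             drop = FALSE]
  rownames(out) <- NULL
  if (is.null(path)) return(out)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' @export
print.sar_curve <- function(x, ...) {
  cat(sprintf("SAR curve [%s downscaling, %s SAD], depths 0..%d\n",
              attr(x, "downscaling"), attr(x, "sad_source"), max(x$depth)))
  print.data.frame(x, digits = 6, row.names = FALSE)
  invisible(x)
}
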