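## Synthetic stem maps with controlled abundance structure and intraspecific
## aggregation. Three placement modes bracket the aggregation regimes of
## real vegetation plots:
##   random -- complete spatial randomness (CSR), the least aggregated;
##   heap   -- the bisection allocation process whose quadrat occupancy law
##             is exactly the recursive occupancy pmf: at each halving, all
##             q + 1 splits of q individuals between the two halves are
##             equally likely;
##   thomas -- a Thomas cluster process (uniform parents, Gaussian
##             offspring, toroidal wrap), the most aggregated at small
##             cluster spread.
## Every generator is deterministic given its seed and conserves S and N
## exactly.

#' Placement specification for synthetic communities
#'
#' @param mode `"random"`, `"heap"` or `"thomas"`.
#' @param seed integer seed; mandatory, every placement is stochastic.
#' @param heap_depth bisections used by heap placement (default 8: quadrat
#'   occupancy then matches the recursive model at all depths up to 8; set
#'   it to the analysis `max_depth`).
#' @param cluster_sd (thomas) offspring standard deviation as a fraction of
#'   the short plot side.
#' @param mean_per_cluster (thomas) mean individuals per cluster parent.
#' @return a `placement_spec` list.
#' @export
placement_spec <- function(mode = c("random", "heap", "thomas"), seed,
                           heap_depth = 8L, cluster_sd = 0.05,
                           mean_per_cluster = 10) {
  mode <- match.arg(mode)
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("placement_spec requires an explicit integer seed", call. = FALSE)
  }
  if (mode == "thomas" && (cluster_sd <= 0 || mean_per_cluster < 1)) {
    stop("thomas mode needs cluster_sd > 0 and mean_per_cluster >= 1",
         call. = FALSE)
  }
  if (mode == "heap" && (heap_depth < 1 || heap_depth != floor(heap_depth))) {
    stop("heap mode needs an integer heap_depth >= 1", call. = FALSE)
  }
  structure(list(mode = mode, seed = as.integer(seed),
                 heap_depth = as.integer(heap_depth),
                 cluster_sd = cluster_sd,
                 mean_per_cluster = mean_per_cluster),
            class = "placement_spec")
}

#' Deterministic rank-abundance vector from the METE SAD
#'
#' Takes `S0` quantile-spaced draws (plotting positions `(k - 1/2)/S0`) from
#' the truncated log-series solved at `(S0, N0)`, then nudges ranks by unit
#' increments until the vector sums to exactly `N0`. Additions go to the top
#' rank; subtractions come off the currently largest rank so no entry drops
#' below 1, keeping the tail shape faithful.
#'
#' @param S0,N0 positive integers, `N0 >= S0`.
#' @return integer vector, length `S0`, non-increasing, summing to `N0`.
#' @examples
#' expected_sad_abundances(5, 5)    # all singletons
#' sum(expected_sad_abundances(24, 37182))  # 37182
#' @export
expected_sad_abundances <- function(S0, N0) {
  if (S0 < 1 || S0 != floor(S0) || N0 != floor(N0)) {
    stop("S0 and N0 must be positive integers", call. = FALSE)
  }
  if (N0 < S0) stop("N0 must be >= S0", call. = FALSE)
  S0 <- as.integer(S0)
  if (S0 == N0) return(rep(1L, S0))
  sad <- solve_sad(S0, N0)
  cdf <- cumsum(sad$probs)
  p <- (seq_len(S0) - 0.5) / S0
  ab <- findInterval(p, cdf, left.open = TRUE) + 1L   # inverse CDF
  ab <- sort(ab, decreasing = TRUE)
  diff <- N0 - sum(ab)
  if (diff > 0) {
    ab[1] <- ab[1] + diff
  } else {
    while (diff < 0) {
      i <- which.max(ab)
      take <- min(-diff, ab[i] - 1L)
      if (take == 0L) stop("cannot reduce abundances below 1", call. = FALSE)
      ab[i] <- ab[i] - take
      diff <- diff + take
    }
  }
  sort(as.integer(ab), decreasing = TRUE)
}

## HEAP allocation of n individuals over the 2^depth terminal cells of the
## longer-side bisection grid. Returns per-cell counts in the same cell
## order as quadrat_index() at that depth.
heap_cell_counts <- function(n, lx, ly, depth) {
  counts <- n
  nx <- 1L
  ny <- 1L
  for (i in seq_len(depth)) {
    split_x <- lx / nx >= ly / ny
    ## counts are ordered by (ix, iy) with iy fastest, matching
    ## quadrat_index; an x-split interleaves columns, a y-split rows.
    left <- integer(length(counts))
    pos <- counts > 0
    left[pos] <- vapply(counts[pos],
                        function(q) sample.int(q + 1L, 1L) - 1L, integer(1))
    if (split_x) {
      ## cell (ix, iy) -> (2ix, iy) and (2ix + 1, iy)
      m <- matrix(counts, nrow = ny)          # ny x nx, iy fastest
      ml <- matrix(left, nrow = ny)
      stacked <- matrix(0L, nrow = ny, ncol = 2L * nx)
      stacked[, seq(1, 2L * nx, by = 2L)] <- ml
      stacked[, seq(2, 2L * nx, by = 2L)] <- m - ml
      new <- as.integer(stacked)
      nx <- nx * 2L
    } else {
      m <- matrix(counts, nrow = ny)
      ml <- matrix(left, nrow = ny)
      stacked <- matrix(0L, nrow = 2L * ny, ncol = nx)
      stacked[seq(1, 2L * ny, by = 2L), ] <- ml
      stacked[seq(2, 2L * ny, by = 2L), ] <- m - ml
      new <- as.integer(stacked)
      ny <- ny * 2L
    }
    counts <- new
  }
  counts
}

#' Generate a synthetic stem map
#'
#' Places each species' individuals independently according to the placement
#' mode; the output has exactly `sum(abundances)` records and each species
#' exactly its stated abundance. Identical inputs and seed give identical
#' output. Calls `set.seed()`, so the session RNG state is modified.
#'
#' @param abundances vector of positive integer per-species abundances.
#' @param extent `c(lx, ly)`; must be square or 2:1.
#' @param placement a [placement_spec()].
#' @return a `stem_map` with species labelled `sp001, sp002, ...` in rank
#'   order of the abundance vector.
#' @export
generate_community <- function(abundances, extent, placement) {
  validate_abundances(abundances)
  stopifnot(inherits(placement, "placement_spec"))
  extent <- as.numeric(extent)
  lx <- extent[1]
  ly <- extent[2]
  asp <- max(lx, ly) / min(lx, ly)
  if (!(abs(asp - 1) < .mete_tol$aspect || abs(asp - 2) < .mete_tol$aspect)) {
    stop("extent must be square or 2:1", call. = FALSE)
  }
  set.seed(placement$seed)
  S <- length(abundances)
  labels <- sprintf("sp%03d", seq_len(S))
  xs <- vector("list", S)
  ys <- vector("list", S)
  for (j in seq_len(S)) {
    n <- as.integer(abundances[j])
    if (placement$mode == "random") {
      xs[[j]] <- stats::runif(n, 0, lx)
      ys[[j]] <- stats::runif(n, 0, ly)
    } else if (placement$mode == "heap") {
      d <- placement$heap_depth
      counts <- heap_cell_counts(n, lx, ly, d)
      div <- grid_divisions(lx, ly, d)
      nx <- div[["nx"]]
      ny <- div[["ny"]]
      cell <- rep(seq_along(counts), counts)       # 1-based, iy fastest
      ix <- (cell - 1L) %/% ny
      iy <- (cell - 1L) %% ny
      xs[[j]] <- (ix + stats::runif(n)) * (lx / nx)
      ys[[j]] <- (iy + stats::runif(n)) * (ly / ny)
    } else {  # thomas
      npar <- max(1L, as.integer(round(n / placement$mean_per_cluster)))
      px <- stats::runif(npar, 0, lx)
      py <- stats::runif(npar, 0, ly)
      par <- sample.int(npar, n, replace = TRUE)
      sd <- placement$cluster_sd * min(lx, ly)
      xs[[j]] <- (px[par] + stats::rnorm(n, 0, sd)) %% lx
      ys[[j]] <- (py[par] + stats::rnorm(n, 0, sd)) %% ly
    }
  }
  stem_map(unlist(xs), unlist(ys), rep(labels, abundances), lx, ly)
}

#' Build a suite of benchmark communities
#'
#' One synthetic community per `(S0, N0, aspect)` specification, each with a
#' log-series rank-abundance vector and a seed derived deterministically
#' from the placement seed. The default suite spans the extremes of the
#' state-variable ranges typical of published vegetation plots
#' (`S0` 7--301, `N0` 669--205096).
#'
#' @param site_specs list of lists with `S0`, `N0` and `aspect` (`"square"`
#'   or `"2:1"`); `NULL` uses the default suite.
#' @param placement a [placement_spec()]; per-site seeds are
#'   `seed + site index`.
#' @return named list of `stem_map`s.
#' @export
make_benchmark_suite <- function(site_specs = NULL, placement) {
  stopifnot(inherits(placement, "placement_spec"))
  if (is.null(site_specs)) site_specs <- default_benchmark_specs()
  if (!length(site_specs)) return(list())
  out <- vector("list", length(site_specs))
  names(out) <- vapply(seq_along(site_specs), function(i) {
    sp <- site_specs[[i]]
    sprintf("site%02d_S%d_N%d", i, sp$S0, sp$N0)
  }, character(1))
  for (i in seq_along(site_specs)) {
    sp <- site_specs[[i]]
    if (sp$N0 < sp$S0) stop("site spec has N0 < S0", call. = FALSE)
    extent <- if (identical(sp$aspect, "2:1")) c(2, 1) else c(1, 1)
    pl <- placement
    pl$seed <- placement$seed + i
    out[[i]] <- generate_community(expected_sad_abundances(sp$S0, sp$N0),
                                   extent, pl)
  }
  out
}

#' @rdname make_benchmark_suite
#' @export
default_benchmark_specs <- function() {
  list(
    list(S0 = 7L,   N0 = 669L,    aspect = "square"),  # fewest species / individuals
    list(S0 = 24L,  N0 = 37182L,  aspect = "square"),  # extreme N0/S0 (grassland-like)
    list(S0 = 48L,  N0 = 3394L,   aspect = "2:1"),     # mid-range temperate forest
    list(S0 = 301L, N0 = 205096L, aspect = "2:1")      # richest / largest plot
  )
}
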