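# Independent oracles: every routine here deliberately avoids the package's
# own code paths (plain polynomial sums instead of lambda-space expm1;
# explicit rectangle bookkeeping instead of integer grid indexing; direct
# Monte-Carlo simulation of the HEAP allocation process).

# Mean of the truncated geometric pmf via the raw polynomial ratio.
oracle_pi_mean <- function(x, n0) {
  n <- 0:n0
  w <- x^n
  sum(n * w) / sum(w)
}

# Multiplier by bisection on x in (0, 1] against the polynomial mean.
oracle_pi_multiplier <- function(n0, area_fraction, iters = 200) {
  target <- n0 * area_fraction
  lo <- 0
  hi <- 1
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (oracle_pi_mean(mid, n0) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

oracle_vacancy <- function(n0, area_fraction) {
  x <- oracle_pi_multiplier(n0, area_fraction)
  1 / sum(x^(0:n0))
}

# Mean of the truncated log-series via bisection on the raw sums.
oracle_sad_x <- function(S0, N0, iters = 200) {
  M <- floor(N0)
  n <- seq_len(M)
  target <- N0 / S0
  # raw sums overflow for x > 1 at large M; rescale by the largest term
  mean_at <- function(x) {
    w <- exp(n * log(x) - log(n) - max(n * log(x) - log(n)))
    sum(w * n) / sum(w)
  }
  lo <- 0
  hi <- 1
  while (mean_at(hi) < target) hi <- hi * 2
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (mean_at(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Monte-Carlo HEAP allocation: follow one quadrat lineage through `depth`
# halvings; at each halving every split of q individuals is equally likely,
# so the retained count is uniform on 0..q. Returns `reps` draws of the
# depth-level occupancy count. Caller controls the RNG seed.
sim_heap_counts <- function(n0, depth, reps) {
  q <- rep(n0, reps)
  for (i in seq_len(depth)) {
    q <- floor(stats::runif(reps) * (q + 1))
  }
  q
}

# Brute-force nested SAR: explicit rectangle lists and point-in-rectangle
# tests ([lo, hi) with the global maximum edge closed).
brute_sar_richness <- function(sm, max_depth) {
  LX <- sm$extent[["lx"]]
  LY <- sm$extent[["ly"]]
  rec <- sm$records
  rects <- list(c(0, 0, LX, LY))
  out <- numeric(max_depth + 1)
  count_depth <- function(rects) {
    tot <- 0
    for (r in rects) {
      inx <- rec$x >= r[1] & (rec$x < r[1] + r[3] |
                                (abs(r[1] + r[3] - LX) < 1e-12 & rec$x == LX))
      iny <- rec$y >= r[2] & (rec$y < r[2] + r[4] |
                                (abs(r[2] + r[4] - LY) < 1e-12 & rec$y == LY))
      tot <- tot + length(unique(rec$species[inx & iny]))
    }
    tot / length(rects)
  }
  out[1] <- count_depth(rects)
  for (i in seq_len(max_depth)) {
    rects <- do.call(c, lapply(rects, function(r) {
      if (r[3] >= r[4]) {
        list(c(r[1], r[2], r[3] / 2, r[4]),
             c(r[1] + r[3] / 2, r[2], r[3] / 2, r[4]))
      } else {
        list(c(r[1], r[2], r[3], r[4] / 2),
             c(r[1], r[2] + r[4] / 2, r[3], r[4] / 2))
      }
    }))
    out[i + 1] <- count_depth(rects)
  }
  out
}

# The 4-stem toy plot: species A at (.1,.1) and (.6,.6), B at (.1,.6),
# C at (.9,.2) on the unit square.
toy_map <- function() {
  stem_map(c(0.1, 0.6, 0.1, 0.9), c(0.1, 0.6, 0.6, 0.2),
           c("A", "A", "B", "C"), 1, 1)
}

# Random small stem map for oracle-equivalence sweeps.
random_fixture <- function(seed) {
  set.seed(seed)
  n <- sample(5:200, 1)
  twotoone <- sample(c(TRUE, FALSE), 1)
  lx <- if (twotoone) 2 else 1
  stem_map(runif(n, 0, lx), runif(n), sample(LETTERS[1:8], n, TRUE), lx, 1)
}
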