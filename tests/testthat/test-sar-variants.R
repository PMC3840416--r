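# The four SAR prediction variants.

test_that("non-recursive observed variant matches per-species assembly", {
  cv <- sar_nonrecursive_observed(1, max_depth = 1)
  expect_equal(cv$richness, c(1, 0.5), tolerance = 1e-14)
  cv <- sar_nonrecursive_observed(c(1, 10), max_depth = 2)
  expect_equal(cv$richness[1], 2)
  expect_equal(cv$richness[3],
               (1 - oracle_vacancy(1, 0.25)) + (1 - oracle_vacancy(10, 0.25)),
               tolerance = 1e-9)
  expect_equal(cv$abundance, 11 * 2^-(0:2))
  expect_error(sar_nonrecursive_observed(integer(0), 2), "at least one")
  expect_error(sar_nonrecursive_observed(c(1, 0), 2), "positive integers")
})

test_that("recursive observed variant matches hand recursion values", {
  cv <- sar_recursive_observed(c(1, 10), max_depth = 2)
  # depth 2 vacancy of n0 = 10 under one extra halving: H_11 / 11
  H11 <- sum(1 / (1:11))
  expect_equal(cv$richness[3], 0.25 + (1 - H11 / 11), tolerance = 1e-12)
  # and via the pmf constructor directly
  per_sp <- vapply(c(1, 10), function(n0)
    1 - occupancy_pmf_recursive(n0, 2)$probs[1], numeric(1))
  expect_equal(cv$richness[3], sum(per_sp), tolerance = 1e-14)
})

test_that("richness is bounded, anchored at S0 and declines monotonically", {
  set.seed(11)
  for (rep in 1:5) {
    ab <- sample(1:80, sample(3:20, 1), replace = TRUE)
    for (f in list(sar_nonrecursive_observed, sar_recursive_observed)) {
      cv <- f(ab, max_depth = 6)
      expect_equal(cv$richness[1], length(ab))
      expect_true(all(cv$richness > 0 & cv$richness <= length(ab)))
      expect_true(all(diff(cv$richness) < 0))
    }
  }
})

test_that("theoretical variants assemble from oracle SAD and vacancies", {
  st <- list(S0 = 4, N0 = 16)
  cv <- sar_nonrecursive_theoretical(st, max_depth = 2)
  expect_equal(cv$richness[1], 4)
  # independent assembly at depth 1: uniform half-area vacancy 1/(n+1)
  x <- oracle_sad_x(4, 16)
  n <- 1:16
  phi <- (x^n / n) / sum(x^n / n)
  expect_equal(cv$richness[2], 4 * sum((n / (n + 1)) * phi), tolerance = 1e-8)
  # depth 2 via oracle vacancies
  v2 <- vapply(n, oracle_vacancy, numeric(1), area_fraction = 0.25)
  expect_equal(cv$richness[3], 4 * sum((1 - v2) * phi), tolerance = 1e-8)
  expect_true(all(diff(cv$richness) < 0))
  expect_error(sar_nonrecursive_theoretical(list(S0 = 10, N0 = 5), 2), "N0")
})

test_that("recursive theoretical variant matches an independent hand iteration", {
  cv <- sar_recursive_theoretical(list(S0 = 4, N0 = 16), max_depth = 3)
  # spreadsheet-style manual pass using only the oracle SAD solver
  S <- 4
  N <- 16
  manual <- S
  for (i in 1:3) {
    x <- oracle_sad_x(S, N)
    M <- floor(N)
    n <- seq_len(M)
    phi <- (x^n / n) / sum(x^n / n)
    S <- S * sum((n / (n + 1)) * phi)
    N <- N / 2
    manual <- c(manual, S)
  }
  expect_equal(cv$richness, manual, tolerance = 1e-8)
  expect_equal(cv$abundance, 16 * 2^-(0:3))
})

test_that("recursive theoretical curve truncates when the state degenerates", {
  expect_message(cv <- sar_recursive_theoretical(list(S0 = 3, N0 = 6), 10),
                 "truncated")
  expect_lt(max(cv$depth), 10)
  expect_true(all(cv$richness >= 1))
})

test_that("depth-1 coincidence holds within each SAD source", {
  ab <- c(3, 3, 7, 20, 41)
  expect_equal(sar_recursive_observed(ab, 1)$richness[2],
               sar_nonrecursive_observed(ab, 1)$richness[2],
               tolerance = 1e-14)
  st <- list(S0 = 12, N0 = 400)
  expect_equal(sar_recursive_theoretical(st, 1)$richness[2],
               sar_nonrecursive_theoretical(st, 1)$richness[2],
               tolerance = 1e-14)
})

test_that("predict_all_variants orchestrates the variant set", {
  # theoretical-only call
  two <- predict_all_variants(state = list(S0 = 10, N0 = 250), max_depth = 3)
  expect_named(two, c("nonrecursive_theoretical", "recursive_theoretical"))
  # full call on a self-consistent community
  ab <- expected_sad_abundances(10, 250)
  four <- predict_all_variants(abundances = ab, max_depth = 3)
  expect_length(four, 4)
  expect_true(all(vapply(four, nrow, integer(1)) == 4L))
  # observed pair at one bisection equals the half-area occupancy sum
  expect_equal(four$nonrecursive_observed$richness[2],
               sum(ab / (ab + 1)), tolerance = 1e-12)
  expect_equal(four$recursive_observed$richness[2],
               sum(ab / (ab + 1)), tolerance = 1e-12)
  # inconsistent state vs abundances
  expect_error(predict_all_variants(state = list(S0 = 3, N0 = 250),
                                    abundances = ab, max_depth = 2),
               "inconsistent")
  expect_error(predict_all_variants(), "supply")
})

test_that("every variant sits below the random-placement SAR", {
  ab <- expected_sad_abundances(15, 600)
  four <- predict_all_variants(abundances = ab, max_depth = 5)
  for (i in 1:5) {
    csr <- sum(1 - (1 - 2^-i)^ab)
    for (cv in four) {
      expect_lte(cv$richness[cv$depth == i], csr + 1e-10)
    }
  }
})

test_that("recursive-observed never exceeds non-recursive-observed beyond depth 1", {
  set.seed(23)
  for (rep in 1:6) {
    S0 <- sample(7:100, 1)
    N0 <- S0 * sample(3:60, 1)
    ab <- expected_sad_abundances(S0, N0)
    rec <- sar_recursive_observed(ab, 6)$richness
    nonrec <- sar_nonrecursive_observed(ab, 6)$richness
    expect_true(all(rec[3:7] <= nonrec[3:7] + 1e-10),
                label = sprintf("S0 = %d, N0 = %d", S0, N0))
  }
})

test_that("SAR tables serialise deterministically", {
  curves <- predict_all_variants(state = list(S0 = 8, N0 = 120), max_depth = 2)
  df <- write_sar_table(curves)
  expect_named(df, c("depth", "area_fraction", "richness", "abundance",
                     "variant_downscaling", "variant_sad"))
  expect_equal(nrow(df), 6)
  f <- tempfile(fileext = ".csv")
  write_sar_table(curves, f)
  back <- utils::read.csv(f)
  expect_equal(back$richness, df$richness, tolerance = 1e-12)
})

test_that("default depth heuristic tracks community size", {
  expect_equal(default_max_depth(16), 2L)
  expect_equal(default_max_depth(205096), 14L)
  expect_equal(default_max_depth(5), 1L)
})
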