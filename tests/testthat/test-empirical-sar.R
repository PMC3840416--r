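# Stem-map I/O and nested (Type IIA) quadrat SAR construction.

test_that("the bundled toy stem map parses and yields the hand-counted SAR", {
  f <- system.file("extdata", "toy_stem_map.csv", package = "metesar")
  sm <- read_stem_map(f)                  # extent from the JSON sidecar
  expect_s3_class(sm, "stem_map")
  expect_equal(nrow(sm$records), 4)
  expect_equal(length(unique(sm$records$species)), 3)
  cv <- nested_grid_sar(sm, 2)
  expect_equal(cv$richness, c(3, 2, 1))   # whole plot; {A,B}|{A,C}; 1 each
  expect_equal(cv$abundance, c(4, 2, 1))
})

test_that("reader validates structure and coordinates", {
  d <- tempfile()
  dir.create(d)
  # coordinate outside extent is a hard error
  f1 <- file.path(d, "bad.csv")
  writeLines(c("x,y,species", "0.5,0.5,A", "1.5,0.2,B"), f1)
  expect_error(read_stem_map(f1, lx = 1, ly = 1), "outside")
  # missing column
  f2 <- file.path(d, "cols.csv")
  writeLines(c("x,y", "0.5,0.5"), f2)
  expect_error(read_stem_map(f2, lx = 1, ly = 1), "columns")
  # empty table
  f3 <- file.path(d, "empty.csv")
  writeLines("x,y,species", f3)
  expect_error(read_stem_map(f3, lx = 1, ly = 1), "empty")
  # malformed coordinate rows are dropped with a message
  f4 <- file.path(d, "malformed.csv")
  writeLines(c("x,y,species", "0.5,0.5,A", "oops,0.2,B", "0.1,0.9,C"), f4)
  expect_message(sm <- read_stem_map(f4, lx = 1, ly = 1), "dropped 1")
  expect_equal(nrow(sm$records), 2)
  # tab-separated input and extent inference
  f5 <- file.path(d, "tabs.tsv")
  writeLines(c("x\ty\tspecies", "1\t0.5\tA", "2\t1\tB"), f5)
  sm5 <- read_stem_map(f5, infer_extent = TRUE)
  expect_equal(unname(sm5$extent), c(2, 1))
})

test_that("stem map round-trips through write/read with sidecar extent", {
  sm <- toy_map()
  f <- tempfile(fileext = ".csv")
  write_stem_map(sm, f)
  back <- read_stem_map(f)
  expect_equal(back$records, sm$records)
  expect_equal(back$extent, sm$extent)
})

test_that("toy plot bisects by hand: x first, then y", {
  sm <- toy_map()
  cv <- nested_grid_sar(sm, 1)
  expect_equal(cv$richness[2], 2)         # {A,B} left, {A,C} right
})

test_that("grid SAR equals the brute-force rectangle oracle", {
  for (seed in 1:20) {
    sm <- random_fixture(seed)
    cv <- nested_grid_sar(sm, 5)
    expect_equal(cv$richness, brute_sar_richness(sm, 5),
                 tolerance = 1e-12, label = sprintf("fixture %d", seed))
  }
})

test_that("individuals are conserved and boundaries counted once", {
  # points exactly on the maximum edges belong to the last quadrat
  sm <- stem_map(c(1, 0.5, 0), c(1, 0.5, 0), c("A", "B", "C"), 1, 1)
  for (i in 0:4) {
    cv <- nested_grid_sar(sm, max(i, 1))
    expect_equal(cv$abundance * 2^cv$depth, rep(3, nrow(cv)))
  }
})

test_that("record order never changes the SAR", {
  sm <- random_fixture(99)
  set.seed(1)
  perm <- sample(nrow(sm$records))
  sm2 <- stem_map(sm$records$x[perm], sm$records$y[perm],
                  sm$records$species[perm],
                  sm$extent[["lx"]], sm$extent[["ly"]])
  expect_equal(nested_grid_sar(sm2, 5)$richness,
               nested_grid_sar(sm, 5)$richness)
})

test_that("non-conforming aspect ratios are rejected with guidance", {
  sm <- stem_map(c(0.1, 2.9), c(0.1, 0.9), c("A", "B"), 3, 1)
  expect_error(nested_grid_sar(sm, 2), "extract_subplots")
})

test_that("subplot extraction re-anchors and validates rectangles", {
  sm <- toy_map()
  left <- extract_subplots(sm, list(c(0, 0, 0.5, 1)))[[1]]  # 2:1 tall
  expect_equal(nrow(left$records), 2)
  expect_equal(sort(left$records$species), c("A", "B"))
  expect_equal(left$records$x, c(0.1, 0.1))  # re-anchored (origin unchanged)
  whole <- extract_subplots(sm, list(c(0, 0, 1, 1)))[[1]]
  expect_equal(whole$records, sm$records)
  expect_error(extract_subplots(sm, list(c(0, 0, 0, 1))), "zero-area")
  expect_error(extract_subplots(sm, list(c(0.5, 0, 1, 1))), "outside")
  expect_error(extract_subplots(sm, list(c(0, 0, 0.9, 0.3))), "square or 2:1")
  expect_warning(extract_subplots(sm, list(c(0, 0, 1, 1), c(0, 0, 0.5, 1))),
                 "overlap")
})

test_that("curve averaging produces fractional state variables", {
  a <- sar_curve(0:2, c(174, 80, 30), c(1000, 500, 250))
  b <- sar_curve(0:2, c(175, 90, 40), c(1200, 600, 300))
  avg <- average_curves(list(a, b))
  expect_equal(avg$richness, c(174.5, 85, 35))
  expect_equal(avg$abundance, c(1100, 550, 275))
  expect_equal(average_curves(list(a))$richness, a$richness)
  expect_equal(average_curves(list(a, a))$richness, a$richness)
  expect_error(average_curves(list(a, sar_curve(0:1, c(175, 90), c(1, 1)))),
               "mismatched")
  expect_error(average_curves(list()), "no curves")
})
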