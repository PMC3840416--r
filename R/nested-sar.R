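## Fully nested (Type IIA) species-area curves: at bisection depth i the
## plot is partitioned into all 2^i congruent quadrats produced by
## successive halvings, and richness is averaged over the complete grid
## (empty quadrats count as richness 0 -- they are valid samples).
##
## Bisection always splits every current quadrat across its longer side;
## a square (tie) splits across x. After the first split of a 2:1 plot the
## longer-side rule forces the axes to alternate, reproducing the standard
## square/2:1 nesting. Quadrat membership uses half-open intervals [lo, hi)
## with points on the plot's maximum edge assigned to the last quadrat, so
## every stem is counted exactly once at every depth.

## Number of grid divisions (nx, ny) after `depth` longer-side bisections.
grid_divisions <- function(lx, ly, depth) {
  nx <- 1L
  ny <- 1L
  for (i in seq_len(depth)) {
    if (lx / nx >= ly / ny) nx <- nx * 2L else ny <- ny * 2L
  }
  c(nx = nx, ny = ny)
}

## 1-based quadrat index per record at the given divisions.
quadrat_index <- function(x, y, lx, ly, nx, ny) {
  ix <- pmin(floor(x / (lx / nx)), nx - 1L)
  iy <- pmin(floor(y / (ly / ny)), ny - 1L)
  as.integer(ix * ny + iy + 1L)
}

#' Nested-grid (Type IIA) species-area curve from a stem map
#'
#' At each depth `i = 0..max_depth` the plot is bisected into `2^i` congruent
#' quadrats and the mean richness (distinct species per quadrat) and mean
#' abundance (individuals per quadrat) over the full grid are recorded.
#' The plot must be square or 2:1 so quadrats stay congruent under halving.
#'
#' @param sm a `stem_map`.
#' @param max_depth number of bisections; integer `>= 1`.
#' @return a `sar_curve` (downscaling/SAD attributes set to `"observed"`).
#' @examples
#' sm <- stem_map(c(.1, .6, .1, .9), c(.1, .6, .6, .2),
#'                c("A", "A", "B", "C"), 1, 1)
#' nested_grid_sar(sm, 2)
#' @export
nested_grid_sar <- function(sm, max_depth) {
  stopifnot(inherits(sm, "stem_map"))
  max_depth <- check_max_depth(max_depth)
  if (!aspect_ok(sm)) {
    stop("plot aspect ratio must be 1:1 or 2:1 for nested bisection; ",
         "use extract_subplots() to carve a conforming subplot", call. = FALSE)
  }
  lx <- sm$extent[["lx"]]
  ly <- sm$extent[["ly"]]
  rec <- sm$records
  sp <- as.integer(factor(rec$species))
  nsp <- max(sp)
  n <- nrow(rec)
  rich <- numeric(max_depth + 1L)
  abund <- numeric(max_depth + 1L)
  for (i in 0:max_depth) {
    div <- grid_divisions(lx, ly, i)
    ncell <- as.numeric(div[["nx"]]) * div[["ny"]]
    cell <- quadrat_index(rec$x, rec$y, lx, ly, div[["nx"]], div[["ny"]])
    ## distinct (cell, species) pairs summed over cells = total richness mass
    pairs <- unique((cell - 1) * nsp + sp)
    rich[i + 1L] <- length(pairs) / ncell
    abund[i + 1L] <- n / ncell
  }
  sar_curve(0:max_depth, rich, abund,
            downscaling = "observed", sad_source = "observed")
}

#' Average SAR curves across subplots
#'
#' Arithmetic mean of richness and abundance at each depth, the operation
#' that produces fractional state variables (e.g. a depth-0 richness of
#' 174.5 from two subplots with 174 and 175 species).
#'
#' @param curves list of `sar_curve`s sharing an identical depth grid.
#' @return a single averaged `sar_curve` (attributes taken from the first).
#' @export
average_curves <- function(curves) {
  if (!length(curves)) stop("no curves to average", call. = FALSE)
  stopifnot(all(vapply(curves, inherits, logical(1), "sar_curve")))
  depths <- curves[[1]]$depth
  for (cv in curves[-1]) {
    if (!identical(cv$depth, depths)) {
      stop("curves have mismatched depth grids", call. = FALSE)
    }
  }
  nd <- length(depths)
  rich <- rowMeans(matrix(vapply(curves, function(cv) cv$richness,
                                 numeric(nd)), nrow = nd))
  abund <- rowMeans(matrix(vapply(curves, function(cv) cv$abundance,
                                  numeric(nd)), nrow = nd))
  sar_curve(depths, rich, abund,
            downscaling = attr(curves[[1]], "downscaling"),
            sad_source = attr(curves[[1]], "sad_source"))
}
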