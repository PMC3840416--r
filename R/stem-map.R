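## Stem maps: spatially explicit plant census data. A record per individual
## (x, y, species label) plus the rectangular plot extent. Only plots that
## are square or 2:1 can be downscaled by nested bisection, because the
## recursive prediction is defined only at successive halvings.

#' Construct a stem map
#'
#' @param x,y coordinates within `[0, lx] x [0, ly]`.
#' @param species species labels (coerced to character; treated as opaque).
#' @param lx,ly plot extent along x and y, in any consistent distance unit
#'   (only area ratios enter the analysis).
#' @return object of class `stem_map`: list with `records` (data frame
#'   `x, y, species`) and `extent = c(lx, ly)`.
#' @export
stem_map <- function(x, y, species, lx, ly) {
  if (!is.numeric(lx) || !is.numeric(ly) || lx <= 0 || ly <= 0) {
    stop("extent sides must be positive", call. = FALSE)
  }
  x <- as.numeric(x)
  y <- as.numeric(y)
  species <- as.character(species)
  n <- length(x)
  if (n == 0L) stop("a stem map needs at least one record", call. = FALSE)
  if (length(y) != n || length(species) != n) {
    stop("x, y and species must have equal length", call. = FALSE)
  }
  bad <- which(!is.finite(x) | !is.finite(y) |
                 x < 0 | x > lx | y < 0 | y > ly)
  if (length(bad)) {
    stop(sprintf("coordinates outside the declared extent at row(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  structure(list(records = data.frame(x = x, y = y, species = species,
                                      stringsAsFactors = FALSE),
                 extent = c(lx = lx, ly = ly)),
            class = "stem_map")
}

#' @export
print.stem_map <- function(x, ...) {
  cat(sprintf("Stem map: %d individuals, %d species, extent %g x %g\n",
              nrow(x$records), length(unique(x$records$species)),
              x$extent[["lx"]], x$extent[["ly"]]))
  invisible(x)
}

aspect_ok <- function(sm) {
  r <- max(sm$extent) / min(sm$extent)
  abs(r - 1) < .mete_tol$aspect || abs(r - 2) < .mete_tol$aspect
}

#' Read a stem map from delimited text
#'
#' Expects columns `x`, `y`, `species` (header required; comma or tab
#' separated, sniffed from the first line). The plot extent comes from, in
#' order of precedence: the `lx`/`ly` arguments; a JSON sidecar
#' `<path>.json` containing `{"lx": ..., "ly": ...}`; or, with
#' `infer_extent = TRUE`, the coordinate maxima. Rows with non-numeric or
#' missing coordinates are dropped with a message; coordinates outside the
#' declared extent are a hard error (never silently clamped).
#'
#' @param path file path.
#' @param lx,ly plot extent; `NULL` to use the sidecar or inference.
#' @param infer_extent take the extent from the data maxima (last resort).
#' @return a `stem_map`.
#' @export
read_stem_map <- function(path, lx = NULL, ly = NULL, infer_extent = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "")
  need <- c("x", "y", "species")
  if (!all(need %in% names(df))) {
    stop("input must have columns x, y, species (found: ",
         paste(names(df), collapse = ", "), ")", call. = FALSE)
  }
  if (nrow(df) == 0L) stop("empty stem map file: ", path, call. = FALSE)
  xs <- suppressWarnings(as.numeric(df$x))
  ys <- suppressWarnings(as.numeric(df$y))
  bad <- !is.finite(xs) | !is.finite(ys) | is.na(df$species)
  if (any(bad)) {
    message(sprintf("read_stem_map: dropped %d malformed row(s)", sum(bad)))
    df <- df[!bad, , drop = FALSE]
    xs <- xs[!bad]
    ys <- ys[!bad]
    if (nrow(df) == 0L) stop("no valid records in ", path, call. = FALSE)
  }
  if (is.null(lx) || is.null(ly)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      lx <- meta$lx
      ly <- meta$ly
    } else if (isTRUE(infer_extent)) {
      lx <- max(xs)
      ly <- max(ys)
    } else {
      stop("plot extent unknown: pass lx/ly, provide a ", sidecar,
           " sidecar, or set infer_extent = TRUE", call. = FALSE)
    }
  }
  stem_map(xs, ys, df$species, lx, ly)
}

#' Write a stem map (and its extent sidecar) to delimited text
#'
#' @param sm a `stem_map`.
#' @param path output file; a JSON sidecar `<path>.json` with the extent is
#'   written alongside.
#' @param sep field separator.
#' @export
write_stem_map <- function(sm, path, sep = ",") {
  stopifnot(inherits(sm, "stem_map"))
  utils::write.table(sm$records, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(lx = sm$extent[["lx"]], ly = sm$extent[["ly"]]),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Extract rectangular subplots from a stem map
#'
#' Mirrors the protocol of carving square or 2:1 subplots out of irregular
#' plots. Records are re-anchored to each subplot's origin; records falling
#' in no rectangle are discarded.
#'
#' @param sm a `stem_map`.
#' @param rects list of rectangles, each `c(x0, y0, lx, ly)` (origin plus
#'   side lengths). Every rectangle must lie within the plot and be square
#'   or 2:1; overlap between rectangles draws a warning.
#' @return list of `stem_map`s, one per rectangle.
#' @export
extract_subplots <- function(sm, rects) {
  stopifnot(inherits(sm, "stem_map"))
  if (!length(rects)) stop("no subplot rectangles supplied", call. = FALSE)
  LX <- sm$extent[["lx"]]
  LY <- sm$extent[["ly"]]
  rects <- lapply(rects, function(r) {
    r <- as.numeric(r)
    if (length(r) != 4L) stop("each rectangle is c(x0, y0, lx, ly)", call. = FALSE)
    if (r[3] <= 0 || r[4] <= 0) stop("zero-area subplot rectangle", call. = FALSE)
    if (r[1] < 0 || r[2] < 0 || r[1] + r[3] > LX + 1e-9 ||
          r[2] + r[4] > LY + 1e-9) {
      stop("subplot rectangle extends outside the plot extent", call. = FALSE)
    }
    asp <- max(r[3:4]) / min(r[3:4])
    if (!(abs(asp - 1) < .mete_tol$aspect || abs(asp - 2) < .mete_tol$aspect)) {
      stop("subplot rectangles must be square or 2:1", call. = FALSE)
    }
    r
  })
  if (length(rects) > 1L) {
    for (i in seq_along(rects)[-1]) {
      for (j in seq_len(i - 1L)) {
        a <- rects[[i]]; b <- rects[[j]]
        if (a[1] < b[1] + b[3] && b[1] < a[1] + a[3] &&
              a[2] < b[2] + b[4] && b[2] < a[2] + a[4]) {
          warning("subplot rectangles overlap; shared stems are duplicated")
        }
      }
    }
  }
  lapply(rects, function(r) {
    rec <- sm$records
    keep <- rec$x >= r[1] & rec$x <= r[1] + r[3] &
      rec$y >= r[2] & rec$y <= r[2] + r[4]
    if (!any(keep)) stop("a subplot rectangle contains no records", call. = FALSE)
    rec <- rec[keep, , drop = FALSE]
    stem_map(rec$x - r[1], rec$y - r[2], rec$species, r[3], r[4])
  })
}
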