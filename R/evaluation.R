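## Scoring predicted against observed SARs with the coefficient of
## determination about the one-to-one line on log-transformed richness:
##   R^2 = 1 - sum (log obs - log pred)^2 / sum (log obs - mean(log obs))^2.
## The statistic can be negative (predictions worse than the observed mean)
## and is invariant to the logarithm base, since both sums rescale by the
## same squared factor. Base 10 is used internally.

#' R-squared about the one-to-one line on log values
#'
#' @param observed,predicted equal-length vectors of positive values
#'   (richness here; any positive quantity in general).
#' @return scalar `<= 1`, possibly negative.
#' @examples
#' r2_one_to_one(c(3, 9, 27), c(3, 9, 27))   # 1
#' r2_one_to_one(c(10, 100), c(10, 10))      # -1
#' @export
r2_one_to_one <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L) {
    stop("observed and predicted must have equal length >= 2", call. = FALSE)
  }
  if (any(!is.finite(observed) | observed <= 0) ||
        any(!is.finite(predicted) | predicted <= 0)) {
    stop("all values must be positive and finite (log transform)", call. = FALSE)
  }
  lo <- log10(observed)
  lp <- log10(predicted)
  ss_tot <- sum((lo - mean(lo))^2)
  if (ss_tot == 0) {
    stop("observed values are all identical; R^2 about the 1:1 line is undefined",
         call. = FALSE)
  }
  1 - sum((lo - lp)^2) / ss_tot
}

variant_keys <- c("nonrecursive_observed", "nonrecursive_theoretical",
                  "recursive_observed", "recursive_theoretical")

#' Evaluate all METE SAR variants against a stem map
#'
#' Runs the full comparison protocol on one community: build the observed
#' nested-grid SAR, read off `S0`, `N0` and the observed abundance vector at
#' the whole-plot scale, predict all four variants on the same depth grid,
#' and score each with [r2_one_to_one()] on the depth-paired richness
#' values. Depth-0 pairs are excluded by default: both sides equal `S0` by
#' construction, so including them only inflates the fit (a switch is
#' provided).
#'
#' @param sm a `stem_map`.
#' @param max_depth number of bisections; default [default_max_depth()] of
#'   the plot's `N0`, capped at 8 for tractability of routine runs.
#' @param include_depth0 include the anchor-scale pair in the score.
#' @return object of class `mete_evaluation`: list with `pairs` (data frame
#'   `depth, variant_downscaling, variant_sad, observed, predicted`), `r2`
#'   (named vector, one entry per variant), `state` (`S0`, `N0`) and
#'   `include_depth0`.
#' @export
evaluate_variants <- function(sm, max_depth = NULL, include_depth0 = FALSE) {
  stopifnot(inherits(sm, "stem_map"))
  if (length(unique(sm$records$species)) < 2L) {
    stop("evaluation needs at least two species (log-richness variance)",
         call. = FALSE)
  }
  N0 <- nrow(sm$records)
  if (is.null(max_depth)) max_depth <- min(8L, default_max_depth(N0))
  max_depth <- check_max_depth(max_depth)
  if (max_depth < 2L && !include_depth0) {
    stop("need at least 2 depths beyond the anchor to score a variant",
         call. = FALSE)
  }
  obs <- nested_grid_sar(sm, max_depth)
  abund <- as.integer(table(sm$records$species))
  preds <- predict_all_variants(abundances = abund, max_depth = max_depth)
  min_depth <- if (include_depth0) 0L else 1L
  pairs <- do.call(rbind, lapply(variant_keys, function(k) {
    pv <- preds[[k]]
    d <- pv$depth[pv$depth >= min_depth]
    data.frame(
      depth = d,
      variant_downscaling = attr(pv, "downscaling"),
      variant_sad = attr(pv, "sad_source"),
      observed = obs$richness[match(d, obs$depth)],
      predicted = pv$richness[match(d, pv$depth)]
    )
  }))
  r2 <- vapply(variant_keys, function(k) {
    p <- pairs[pairs$variant_downscaling == strsplit(k, "_")[[1]][1] &
                 pairs$variant_sad == strsplit(k, "_")[[1]][2], ]
    r2_one_to_one(p$observed, p$predicted)
  }, numeric(1))
  structure(list(pairs = pairs, r2 = r2,
                 state = list(S0 = length(abund), N0 = N0),
                 include_depth0 = include_depth0),
            class = "mete_evaluation")
}

#' @export
print.mete_evaluation <- function(x, ...) {
  cat(sprintf("METE SAR evaluation: S0 = %d, N0 = %d, %d scored depths\n",
              x$state$S0, x$state$N0, length(unique(x$pairs$depth))))
  print(round(sort(x$r2, decreasing = TRUE), 4))
  invisible(x)
}

#' Rank variants across evaluated sites
#'
#' Pools the log richness pairs of every site per variant, computes the
#' pooled R-squared about the one-to-one line, and orders variants by it
#' (descending; ties broken alphabetically by label). Per-site win counts
#' record how often each variant had the highest site-level R-squared.
#'
#' @param results list of `mete_evaluation` objects (one per site).
#' @return data frame with columns `variant`, `pooled_r2`, `site_wins`,
#'   ordered best first.
#' @export
rank_variants <- function(results) {
  if (!length(results)) stop("no evaluation results supplied", call. = FALSE)
  stopifnot(all(vapply(results, inherits, logical(1), "mete_evaluation")))
  pooled <- vapply(variant_keys, function(k) {
    parts <- strsplit(k, "_")[[1]]
    obs <- numeric(0)
    pred <- numeric(0)
    for (res in results) {
      p <- res$pairs[res$pairs$variant_downscaling == parts[1] &
                       res$pairs$variant_sad == parts[2], ]
      obs <- c(obs, p$observed)
      pred <- c(pred, p$predicted)
    }
    r2_one_to_one(obs, pred)
  }, numeric(1))
  wins <- table(factor(vapply(results, function(res) {
    r <- res$r2
    names(r)[order(-r, names(r))][1]
  }, character(1)), levels = variant_keys))
  out <- data.frame(variant = variant_keys,
                    pooled_r2 = pooled,
                    site_wins = as.integer(wins))
  out <- out[order(-out$pooled_r2, out$variant), , drop = FALSE]
  rownames(out) <- NULL
  out
}
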