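# Hartigan's dip test for multimodality. The statistic is the minimal
# sup-norm distance between the empirical CDF and any unimodal CDF; the null
# is calibrated by resampling from the closest unimodal CDF itself.

#' Hartigan's dip statistic
#'
#' The minimal sup-norm distance between the empirical CDF of `x` and the
#' closest unimodal CDF, computed by the iterative greatest-convex-minorant /
#' least-concave-majorant algorithm. Uniform (and any unimodal-compatible)
#' data attain the lower bound `1 / (2 n)`; well separated clusters push the
#' statistic up towards the smaller cluster's mass fraction.
#'
#' @param x numeric vector, at least 2 finite values.
#' @param full logical; if `TRUE` also return the modal interval and hull
#'   touch points (used internally to build the closest unimodal CDF).
#' @return the dip statistic, or a list when `full = TRUE`.
#' @export
#' @examples
#' dip_statistic(c(0, 1)) # 0.25 = 1/(2n)
#' dip_statistic(c(0, 0.01, 0.02, 1, 1.01, 1.02)) # two clusters: large dip
dip_statistic <- function(x, full = FALSE) {
  x <- sort(x[is.finite(x)])
  if (length(x) < 2L) {
    stop(errorCondition("dip_statistic: need at least 2 points",
                        class = c("ghoutliers_too_few", "error")))
  }
  res <- .dip_cpp(x)
  if (full) c(res, list(x = x)) else res$dip
}

# Piecewise-linear closest unimodal CDF from the hull touch points: node
# heights (i - 0.5)/n at touch indices, a straight bridge across the modal
# interval, and clamping at the extremes (equivalent to small end atoms).
unimodal_cdf_nodes <- function(dipres) {
  n <- length(dipres$x)
  idx <- c(dipres$lower_touch,
           dipres$upper_touch[dipres$upper_touch > dipres$low])
  list(p = (idx - 0.5) / n, q = dipres$x[idx])
}

# Inverse-transform sample of size m from the piecewise-linear unimodal CDF.
sample_unimodal <- function(nodes, m) {
  u <- runif(m)
  if (length(nodes$p) == 1L) return(rep(nodes$q, m))
  approx(nodes$p, nodes$q, xout = u, rule = 2, ties = "ordered")$y
}

#' Dip test for multimodality with a unimodal bootstrap null
#'
#' Computes the dip statistic and `n_boot` null statistics from samples of
#' the same size drawn (by inverse transform) from the closest unimodal CDF.
#' The sample is called multimodal when its dip exceeds every null statistic
#' and also exceeds `threshold`, a floor corresponding to multimodality that
#' is barely visible upon inspection. Samples with fewer than `min_unique`
#' distinct values are skipped (reported unimodal): the gate targets
#' discreteness, so distinctness uses exact equality of stored values.
#'
#' @param x numeric vector.
#' @param n_boot number of bootstrap null statistics (default 30).
#' @param threshold absolute dip floor (default 0.0001).
#' @param min_unique minimum number of distinct values (default 60).
#' @param seed optional integer seed for the bootstrap draws.
#' @return a list of class `"dip_result"`: `statistic`, `null_stats`,
#'   `is_multimodal`, `skipped`, `n`, `n_unique`.
#' @export
#' @examples
#' set.seed(1)
#' dip_test(c(rnorm(500), rnorm(500, 8)), seed = 1)$is_multimodal
dip_test <- function(x, n_boot = 30, threshold = 1e-4, min_unique = 60,
                     seed = NULL) {
  x <- x[is.finite(x)]
  n_unique <- length(unique(x))
  if (n_unique < min_unique) {
    return(structure(list(statistic = NA_real_, null_stats = numeric(0),
                          is_multimodal = FALSE, skipped = TRUE,
                          n = length(x), n_unique = n_unique),
                     class = "dip_result"))
  }
  dres <- dip_statistic(x, full = TRUE)
  nodes <- unimodal_cdf_nodes(dres)
  null_stats <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      dip_statistic(sample_unimodal(nodes, length(x)))
    }, numeric(1))
  })
  structure(list(statistic = dres$dip, null_stats = null_stats,
                 is_multimodal = dres$dip > max(null_stats) &&
                   dres$dip > threshold,
                 skipped = FALSE, n = length(x), n_unique = n_unique),
            class = "dip_result")
}

#' @export
print.dip_result <- function(x, ...) {
  if (x$skipped) {
    cat(sprintf("dip test skipped (%d < required unique values)\n", x$n_unique))
  } else {
    cat(sprintf("dip = %.5g (null max %.5g over %d bootstraps): %s\n",
                x$statistic, max(x$null_stats), length(x$null_stats),
                if (x$is_multimodal) "multimodal" else "not multimodal"))
  }
  invisible(x)
}
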