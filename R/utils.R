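# Internal helpers shared across modules.

#' Run code with a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so
#' seeded internals (bootstraps, stochastic EM) do not disturb the global
#' random stream. A `NULL` seed runs `expr` unseeded.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Weighted median
#'
#' Returns the smallest value at which the cumulative weight reaches half of
#' the total; when the half-weight point falls exactly on a boundary the two
#' adjacent values are averaged.
#'
#' @param x numeric values.
#' @param w nonnegative weights, same length as `x`.
#' @return scalar weighted median.
#' @export
#' @examples
#' weighted_median(1:4, c(1, 1, 1, 1)) # 2.5
#' weighted_median(1:3, c(1, 5, 1))    # 2
weighted_median <- function(x, w = rep(1, length(x))) {
  stopifnot(length(x) == length(w), all(w >= 0), any(w > 0))
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  i <- which(cw >= 0.5)[1L]
  if (abs(cw[i] - 0.5) < 1e-12 && i < length(x)) (x[i] + x[i + 1L]) / 2 else x[i]
}

#' Weighted sample quantiles
#'
#' Quantiles of a weighted sample by linear interpolation of the weighted
#' plotting positions p_i = (cumw_i - w_i / 2) / sum(w), the weighted
#' analogue of the mid-point convention used for the percentile grid.
#'
#' @param x numeric values.
#' @param probs probabilities in (0, 1).
#' @param w nonnegative weights.
#' @return numeric vector of quantiles.
#' @keywords internal
#' @noRd
weighted_quantile <- function(x, probs, w = rep(1, length(x))) {
  keep <- w > 0
  x <- x[keep]; w <- w[keep]
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  p <- (cw - w / 2) / cw[length(cw)]
  if (length(x) == 1L) return(rep(x, length(probs)))
  approx(p, x, xout = probs, rule = 2, ties = "ordered")$y
}

# Consistent sample-quantile convention for the whole package: linear
# interpolation of order statistics (R type 7), except where the percentile
# grid explicitly uses the mid-point convention (type 5) so that a sample
# consisting of exact grid quantiles is reproduced exactly.
sample_quantile <- function(x, probs, type = 7) {
  unname(quantile(x, probs = probs, type = type, names = FALSE))
}

stop_degenerate <- function(msg = "degenerate distribution") {
  stop(errorCondition(msg, class = c("ghoutliers_degenerate", "error")))
}

is_degenerate_error <- function(e) inherits(e, "ghoutliers_degenerate")
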