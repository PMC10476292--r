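# Shape classification: a sample is routed as MULTIMODAL, MONOTONIC, or
# UNIMODAL_TWO_SIDED. Multimodality is decided by dip tests on the raw and
# ASO-probit-transformed sample; monotonicity by mirroring the sample about
# the edge its peak sits on and re-testing (a mirrored monotone density is
# unimodal, while a mirrored non-monotone density grows two peaks).

#' Concatenate a sample with its mirror image
#'
#' Returns `c(x, 2 * c - x)`: a sample of size `2 n` exactly symmetric about
#' the reflection point `c`.
#'
#' @param x numeric vector.
#' @param c finite reflection point.
#' @return numeric vector of length `2 * length(x)`.
#' @export
#' @examples
#' mirror_concat(c(1, 2, 3), 1) # 1 2 3 1 0 -1
mirror_concat <- function(x, c) {
  stopifnot(is.finite(c))
  c(x, 2 * c - x)
}

#' Half-sample mode estimator
#'
#' Recursively keeps the shortest half of the sorted sample until at most
#' three points remain; deterministic given the sorted sample (the first of
#' several equally short windows is kept).
#'
#' @param x numeric vector with at least 1 finite value.
#' @return scalar mode estimate, always within the sample range.
#' @export
#' @examples
#' estimate_mode(c(0, 0, 0, 1, 5)) # 0
estimate_mode <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0L) stop("estimate_mode: no finite values")
  while (n > 3L) {
    k <- ceiling(n / 2)
    widths <- x[k:n] - x[seq_len(n - k + 1L)]
    i <- which.min(widths)
    x <- x[i:(i + k - 1L)]
    n <- k
  }
  if (n == 1L) return(x)
  if (n == 2L) return(mean(x))
  d1 <- x[2] - x[1]
  d2 <- x[3] - x[2]
  if (d1 < d2) mean(x[1:2]) else if (d2 < d1) mean(x[2:3]) else x[2]
}

#' Split a unimodal sample at its peak
#'
#' @param x numeric vector.
#' @param mode peak location, within the sample range.
#' @param min_side_points minimum points required on each side; fewer raises
#'   a side-too-small error (callers fall back to treating the whole sample
#'   as monotonic).
#' @return list with `lower` (points `<= mode`) and `upper` (points
#'   `>= mode`); points equal to the mode belong to both sides.
#' @export
#' @examples
#' split_at_peak(1:5, 3, min_side_points = 1)
split_at_peak <- function(x, mode, min_side_points = 50) {
  if (mode < min(x) || mode > max(x)) stop("split_at_peak: mode outside range")
  lower <- x[x <= mode]
  upper <- x[x >= mode]
  if (length(lower) < min_side_points || length(upper) < min_side_points) {
    stop(errorCondition("split_at_peak: a side has too few points",
                        class = c("ghoutliers_side_too_small", "error")))
  }
  list(lower = lower, upper = upper)
}

#' Classify the shape of a distribution
#'
#' Routing logic of the detector:
#' \enumerate{
#'   \item dip-test the raw sample and its ASO-probit transform; if either is
#'     multimodal the sample is `MULTIMODAL`.
#'   \item otherwise, if the estimated mode lies within `edge_frac` of the
#'     range of either boundary, mirror the sample about that boundary's
#'     extremum and dip-test the concatenation: if it stays unimodal the
#'     sample is `MONOTONIC` (peaked at that edge).
#'   \item otherwise the sample is `UNIMODAL_TWO_SIDED`.
#' }
#' The mirrored dip test is the final arbiter of monotonicity; `edge_frac`
#' only gates whether the mirror branch is tried.
#'
#' @param x numeric vector.
#' @param n_boot,threshold,min_unique dip-test settings (see [dip_test()]).
#' @param edge_frac fraction of the data range within which the mode counts
#'   as sitting on an edge (default 0.05).
#' @param seed optional integer seed for the dip bootstraps.
#' @return a list of class `"shape_class"`: `label` (one of `"MULTIMODAL"`,
#'   `"MONOTONIC"`, `"UNIMODAL_TWO_SIDED"`), `mode`, and `mirror_edge` (the
#'   boundary extremum, `NA` unless monotonic).
#' @export
#' @examples
#' set.seed(2)
#' classify_shape(rexp(5000), seed = 2)$label # "MONOTONIC"
classify_shape <- function(x, n_boot = 30, threshold = 1e-4, min_unique = 60,
                           edge_frac = 0.05, seed = NULL) {
  x <- x[is.finite(x)]
  mode <- estimate_mode(x)
  seeds <- if (is.null(seed)) list(NULL, NULL, NULL) else as.list(seed + 0:2)
  d_raw <- dip_test(x, n_boot, threshold, min_unique, seed = seeds[[1]])
  d_tr <- tryCatch(
    dip_test(aso_probit(x)$z, n_boot, threshold, min_unique, seed = seeds[[2]]),
    ghoutliers_degenerate = function(e) NULL)
  if (d_raw$is_multimodal || (!is.null(d_tr) && d_tr$is_multimodal)) {
    return(structure(list(label = "MULTIMODAL", mode = mode,
                          mirror_edge = NA_real_), class = "shape_class"))
  }
  rng <- range(x)
  span <- rng[2] - rng[1]
  edge <- if (mode <= rng[1] + edge_frac * span) rng[1]
          else if (mode >= rng[2] - edge_frac * span) rng[2]
          else NA_real_
  if (!is.na(edge)) {
    d_mir <- dip_test(mirror_concat(x, edge), n_boot, threshold, min_unique,
                      seed = seeds[[3]])
    if (!d_mir$is_multimodal) {
      return(structure(list(label = "MONOTONIC", mode = mode,
                            mirror_edge = edge), class = "shape_class"))
    }
  }
  structure(list(label = "UNIMODAL_TWO_SIDED", mode = mode,
                 mirror_edge = NA_real_), class = "shape_class")
}

#' @export
print.shape_class <- function(x, ...) {
  cat(sprintf("shape: %s (mode %.6g%s)\n", x$label, x$mode,
              if (!is.na(x$mirror_edge))
                sprintf(", mirrored at %.6g", x$mirror_edge) else ""))
  invisible(x)
}
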