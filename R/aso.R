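# Asymmetrical outlyingness (ASO): each point's deviation from the median is
# scaled by the half-interquartile spread of that point's own side, so that
# skewed sides become comparable. The ASO scores are then squeezed into (0,1)
# by a range-plus-margin rescale and probit-transformed; a uniform ASO
# distribution maps to an exactly normal score distribution (the property
# holds under any affine rescale of a uniform variate).

#' Robust five-number summary used by the ASO transform
#'
#' @param x numeric sample with at least 4 finite values.
#' @return a list of class `"robust_summary"` with `m` (median), `Q1`, `Q3`,
#'   `lower_half = m - Q1` and `upper_half = Q3 - m`. Quartiles use linear
#'   interpolation of order statistics.
#' @export
#' @examples
#' robust_summary(c(0, 1, 2, 3, 10)) # m = 2, Q1 = 1, Q3 = 3
robust_summary <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4L) {
    stop(errorCondition("robust_summary: need at least 4 points",
                        class = c("ghoutliers_too_few", "error")))
  }
  q <- sample_quantile(x, c(0.25, 0.5, 0.75))
  structure(list(m = q[2], Q1 = q[1], Q3 = q[3],
                 lower_half = q[2] - q[1], upper_half = q[3] - q[2]),
            class = "robust_summary")
}

#' @export
print.robust_summary <- function(x, ...) {
  cat(sprintf("median %.6g, Q1 %.6g, Q3 %.6g (half-spreads %.6g / %.6g)\n",
              x$m, x$Q1, x$Q3, x$lower_half, x$upper_half))
  invisible(x)
}

# Resolve degenerate half-spreads: discrete data commonly collapses one side
# of the IQR onto the median. If one half is 0 the other half substitutes;
# if both are 0 but the sample still has spread, half the full IQR-like
# spread is unavailable, so fall back to half the central 10-90% spread.
aso_scales <- function(rs, x) {
  lh <- rs$lower_half
  uh <- rs$upper_half
  if (lh <= 0 && uh <= 0) {
    iqr <- rs$Q3 - rs$Q1
    if (iqr > 0) {
      lh <- uh <- iqr / 2
    } else {
      spread <- diff(sample_quantile(x, c(0.1, 0.9)))
      if (spread <= 0) stop_degenerate("both half-spreads are zero")
      lh <- uh <- spread / 2
    }
  } else if (lh <= 0) {
    lh <- uh
  } else if (uh <= 0) {
    uh <- lh
  }
  list(lower = lh, upper = uh)
}

#' Signed asymmetrical-outlyingness scores
#'
#' `s_i = (x_i - m) / upper_half` for points at or above the median and
#' `(x_i - m) / lower_half` below it, so `s = 1` exactly at Q3 and `s = -1`
#' at Q1. Scores are location/scale free and rank-preserving.
#'
#' @param x numeric sample (at least 4 finite values, not all equal).
#' @return a list of class `"aso_scores"`: `signed` (the scores), `summary`
#'   (the [robust_summary()]), and `scales` (the half-spreads actually used,
#'   after degenerate-side substitution).
#' @export
#' @examples
#' compute_aso(c(0, 1, 2, 3, 10))$signed # -2 -1 0 1 8
compute_aso <- function(x) {
  rs <- robust_summary(x)
  sc <- aso_scales(rs, x)
  s <- ifelse(x >= rs$m, (x - rs$m) / sc$upper, (x - rs$m) / sc$lower)
  structure(list(signed = s, summary = rs, scales = sc), class = "aso_scores")
}

# Map an original-scale value through the ASO scaling (monotone).
aso_forward <- function(x, aso) {
  ifelse(x >= aso$summary$m,
         (x - aso$summary$m) / aso$scales$upper,
         (x - aso$summary$m) / aso$scales$lower)
}

# Invert the ASO scaling.
aso_inverse <- function(s, aso) {
  ifelse(s >= 0,
         aso$summary$m + s * aso$scales$upper,
         aso$summary$m + s * aso$scales$lower)
}

#' Probit transform of outlyingness scores
#'
#' Rescales scores into (0, 1) by a range-plus-margin affine map,
#' `u = (s - s_min + delta) / (s_max - s_min + 2 delta)` with margin
#' `delta = (s_max - s_min) / (2 n)`, then applies the standard normal
#' quantile function. The margin keeps the probit finite at the sample
#' extremes; the affine map preserves the uniform-to-normal property.
#'
#' @param s numeric vector of finite scores with positive range.
#' @return a list of class `"probit_scores"`: `z` (probit scores), and the
#'   rescale constants `s_min`, `s_max`, `delta` needed to invert the map.
#' @export
probit_transform <- function(s) {
  stopifnot(all(is.finite(s)), length(s) >= 2L)
  s_min <- min(s)
  s_max <- max(s)
  if (s_max <= s_min) stop_degenerate("scores have zero range")
  delta <- (s_max - s_min) / (2 * length(s))
  u <- (s - s_min + delta) / (s_max - s_min + 2 * delta)
  structure(list(z = qnorm(u), s_min = s_min, s_max = s_max, delta = delta),
            class = "probit_scores")
}

# Forward/inverse maps of the probit rescale for threshold back-mapping.
probit_forward <- function(s, pr) {
  qnorm((s - pr$s_min + pr$delta) / (pr$s_max - pr$s_min + 2 * pr$delta))
}

probit_inverse <- function(z, pr) {
  pnorm(z) * (pr$s_max - pr$s_min + 2 * pr$delta) + pr$s_min - pr$delta
}

#' ASO-probit transform of a sample
#'
#' Convenience composition of [compute_aso()] and [probit_transform()]; the
#' returned object records both monotone steps so model-scale thresholds can
#' be mapped back to original units.
#'
#' @param x numeric sample.
#' @return a list of class `"aso_probit"` with `z`, `aso`, and `probit`.
#' @export
aso_probit <- function(x) {
  aso <- compute_aso(x)
  pr <- probit_transform(aso$signed)
  structure(list(z = pr$z, aso = aso, probit = pr), class = "aso_probit")
}

# Original units -> probit scale.
aso_probit_forward <- function(x, ap) {
  probit_forward(aso_forward(x, ap$aso), ap$probit)
}

# Probit scale -> original units.
aso_probit_inverse <- function(z, ap) {
  aso_inverse(probit_inverse(z, ap$probit), ap$aso)
}
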