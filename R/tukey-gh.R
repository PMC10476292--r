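# The Tukey g-and-h family: a standard normal Z is transformed as
#   x = A + B * ((exp(g*Z) - 1) / g) * exp(h * Z^2 / 2),
# where g controls skew (odd moments) and h tail heaviness (even moments).
# g = h = 0 recovers N(A, B^2). Only the monotone regime h >= 0 is supported.

# |g| below this uses the analytic g -> 0 limit, which avoids catastrophic
# cancellation in (exp(g*z) - 1) / g without a visible branch discontinuity.
.G_EPS <- 1e-8

#' Tukey g-and-h parameter set
#'
#' Bundles the four parameters of the Tukey g-and-h distribution: location
#' `A`, scale `B > 0`, skew `g`, and tail heaviness `h >= 0`.
#'
#' @param A real location (the distribution's median).
#' @param B positive scale.
#' @param g real skew parameter; `g = 0` is symmetric.
#' @param h nonnegative tail parameter; `h = 0` has normal-like tails.
#' @return an object of class `"tgh_params"`.
#' @export
#' @examples
#' tgh_params(0, 1, 0.3, 0.1)
tgh_params <- function(A, B, g = 0, h = 0) {
  stopifnot(is.numeric(A), is.numeric(B), is.numeric(g), is.numeric(h),
            length(A) == 1, length(B) == 1, length(g) == 1, length(h) == 1,
            is.finite(A), is.finite(B), is.finite(g), is.finite(h))
  if (B <= 0) stop("tgh_params: B must be positive")
  if (h < 0) stop("tgh_params: h must be nonnegative")
  structure(list(A = A, B = B, g = g, h = h), class = "tgh_params")
}

#' @export
print.tgh_params <- function(x, ...) {
  cat(sprintf("Tukey g-and-h parameters: A = %.6g, B = %.6g, g = %.6g, h = %.6g\n",
              x$A, x$B, x$g, x$h))
  invisible(x)
}

as_tgh <- function(params) {
  if (!inherits(params, "tgh_params")) stop("expected a 'tgh_params' object")
  params
}

#' Tukey g-and-h transform
#'
#' Maps standard-normal quantiles `z` to the g-and-h scale. Strictly
#' increasing in `z` for any `g` when `h >= 0`.
#'
#' @param z numeric vector of standard-normal scale values.
#' @param params a [tgh_params()] object.
#' @return numeric vector, same length as `z`.
#' @export
#' @examples
#' tgh_transform(1.3, tgh_params(5, 2)) # 7.6
tgh_transform <- function(z, params) {
  p <- as_tgh(params)
  core <- if (abs(p$g) < .G_EPS) z else expm1(p$g * z) / p$g
  p$A + p$B * core * exp(p$h * z^2 / 2)
}

# First derivative of the transform with respect to z (always positive for
# h >= 0); used by the density and by Newton inversion.
tgh_deriv <- function(z, params) {
  p <- as_tgh(params)
  e <- exp(p$h * z^2 / 2)
  if (abs(p$g) < .G_EPS) {
    p$B * e * (1 + p$h * z^2)
  } else {
    p$B * e * (exp(p$g * z) + p$h * z * expm1(p$g * z) / p$g)
  }
}

#' Tukey g-and-h quantile function
#'
#' @param p probabilities in (0, 1).
#' @param params a [tgh_params()] object.
#' @return numeric vector of quantiles; `tgh_quantile(0.5, params)` equals
#'   the location `A`.
#' @export
#' @examples
#' tgh_quantile(0.75, tgh_params(0, 1)) # ~0.6745
tgh_quantile <- function(p, params) {
  if (any(p <= 0 | p >= 1)) stop("tgh_quantile: p must lie strictly in (0, 1)")
  tgh_transform(qnorm(p), params)
}

#' Invert the Tukey g-and-h transform
#'
#' Finds `z` with `tgh_transform(z, params) == x` by monotone interpolation
#' on a transform grid followed by damped Newton polishing, with a
#' root-bracketing fallback for any point that fails to converge.
#'
#' @param x numeric vector on the g-and-h scale.
#' @param params a [tgh_params()] object (requires `h >= 0`).
#' @param tol relative tolerance: the result satisfies
#'   `|tgh_transform(z) - x| <= tol * max(1, |x|)`.
#' @return numeric vector of standard-normal scale values.
#' @export
#' @examples
#' tgh_inverse(tgh_transform(1.7, tgh_params(0, 1, 0.4, 0.1)),
#'             tgh_params(0, 1, 0.4, 0.1))
tgh_inverse <- function(x, params, tol = 1e-10) {
  p <- as_tgh(params)
  zg <- seq(-16, 16, by = 0.05)
  tg <- tgh_transform(zg, p)
  ok <- is.finite(tg)
  zg <- zg[ok]; tg <- tg[ok]
  z <- approx(tg, zg, xout = pmin(pmax(x, tg[1]), tg[length(tg)]),
              rule = 2, ties = "ordered")$y
  target_tol <- tol * pmax(1, abs(x))
  for (it in seq_len(60L)) {
    f <- tgh_transform(z, p) - x
    bad <- abs(f) > target_tol
    if (!any(bad)) break
    step <- f[bad] / tgh_deriv(z[bad], p)
    step[!is.finite(step)] <- 0
    z[bad] <- z[bad] - pmin(pmax(step, -0.5), 0.5)
  }
  f <- tgh_transform(z, p) - x
  bad <- which(abs(f) > target_tol)
  for (i in bad) { # bracketing fallback, rarely reached
    lo <- -16; hi <- 16
    while (tgh_transform(lo, p) > x[i] && lo > -700) lo <- lo * 2
    while (tgh_transform(hi, p) < x[i] && hi < 700) hi <- hi * 2
    r <- tryCatch(
      uniroot(function(zz) tgh_transform(zz, p) - x[i], c(lo, hi),
              tol = .Machine$double.eps^0.75),
      error = function(e) NULL)
    if (is.null(r)) {
      stop(sprintf(
        "tgh_inverse: no convergence at x = %g (params A=%g B=%g g=%g h=%g)",
        x[i], p$A, p$B, p$g, p$h))
    }
    z[i] <- r$root
  }
  z
}

# Support of the distribution: when h = 0 and g != 0 the transform is
# bounded on one side (at A - B/g); otherwise the support is the real line.
tgh_support <- function(params) {
  p <- as_tgh(params)
  if (p$h > 0 || abs(p$g) < .G_EPS) return(c(-Inf, Inf))
  bound <- p$A - p$B / p$g
  if (p$g > 0) c(bound, Inf) else c(-Inf, bound)
}

#' Tukey g-and-h density
#'
#' Density by change of variables, `f(x) = dnorm(z) / T'(z)` with
#' `z = tgh_inverse(x)` and `T` the g-and-h transform; zero outside the
#' support (which is half-bounded when `h = 0` and `g != 0`).
#'
#' @param x numeric vector.
#' @param params a [tgh_params()] object.
#' @param log logical; return log-density.
#' @return numeric vector of (log-)densities.
#' @export
tgh_density <- function(x, params, log = FALSE) {
  sup <- tgh_support(params)
  inside <- x > sup[1] & x < sup[2]
  ld <- rep(-Inf, length(x))
  if (any(inside)) {
    z <- tgh_inverse(x[inside], params)
    ld[inside] <- dnorm(z, log = TRUE) - log(tgh_deriv(z, params))
  }
  if (log) ld else exp(ld)
}

#' Tukey g-and-h cumulative distribution function
#'
#' @param x numeric vector.
#' @param params a [tgh_params()] object.
#' @return numeric vector of probabilities.
#' @export
tgh_cdf <- function(x, params) {
  sup <- tgh_support(params)
  out <- numeric(length(x))
  out[x >= sup[2]] <- 1
  inside <- x > sup[1] & x < sup[2]
  if (any(inside)) out[inside] <- pnorm(tgh_inverse(x[inside], params))
  out
}

#' Sample from a Tukey g-and-h distribution
#'
#' Draws `z ~ N(0, 1)` from the current RNG stream and applies the g-and-h
#' transform; reproducible under `set.seed()`.
#'
#' @param n number of draws.
#' @param params a [tgh_params()] object.
#' @return numeric vector of length `n`.
#' @export
tgh_sample <- function(n, params) {
  stopifnot(n >= 1)
  tgh_transform(rnorm(n), params)
}

#' Fit a Tukey g-and-h model by percentile regression
#'
#' Estimates (A, B, g, h) from a grid of `grid_size` sample percentiles at
#' probabilities (i - 0.5) / grid_size:
#' \enumerate{
#'   \item A is the sample median.
#'   \item For each symmetric percentile pair (p, 1 - p) with p > 0.5,
#'     g_p = log((x_p - A) / (A - x_{1-p})) / z_p; g is the weighted median
#'     of the valid g_p (pairs whose half-spread ratio is not positive are
#'     dropped).
#'   \item With g fixed, y_p = g (x_p - x_{1-p}) / (exp(g z_p) - exp(-g z_p))
#'     (limit (x_p - x_{1-p}) / (2 z_p) as g -> 0), and the weighted linear
#'     regression log y_p = log B + h z_p^2 / 2 gives B and h.
#' }
#' Regression and median weights grow linearly toward the upper tail,
#' w_p = 1 + upweight * 2 * (p - 0.5), so the model's tail fits well even
#' when the overall fit is imperfect. Optional shrinkage pulls g and h
#' toward 0 (and h is clamped at 0), which guards against overfitting
#' discrete data.
#'
#' @param x numeric sample, length at least `grid_size`, not constant.
#' @param grid_size number of percentiles (default 100).
#' @param upweight slope of the upper-tail weighting (0 disables).
#' @param shrinkage logical; apply the g/h shrinkage.
#' @param shrink_g,shrink_h shrinkage fractions lambda in `g <- (1 - lambda) g`
#'   and `h <- max(0, (1 - lambda) h)`.
#' @param w optional nonnegative per-observation weights (used by the
#'   responsibility-weighted EM variant); quantiles and the median are then
#'   weighted.
#' @return a [tgh_params()] object.
#' @export
#' @examples
#' set.seed(1)
#' fit_tgh_percentile(tgh_sample(1e4, tgh_params(0, 1, 0.3, 0.1)))
fit_tgh_percentile <- function(x, grid_size = 100, upweight = 1,
                               shrinkage = TRUE, shrink_g = 0.05,
                               shrink_h = 0.05, w = NULL) {
  x <- x[is.finite(x)]
  if (length(x) < grid_size) {
    stop("fit_tgh_percentile: need at least 'grid_size' observations")
  }
  if (max(x) == min(x)) stop_degenerate("constant sample")
  probs <- (seq_len(grid_size) - 0.5) / grid_size
  if (is.null(w)) {
    xq <- sample_quantile(x, probs)
    A <- median(x)
  } else {
    stopifnot(length(w) == length(x) || length(w) == sum(is.finite(x)))
    xq <- weighted_quantile(x, probs, w)
    A <- weighted_quantile(x, 0.5, w)
  }
  hi <- which(probs > 0.5)
  lo <- grid_size + 1L - hi
  zp <- qnorm(probs[hi])
  wp <- 1 + upweight * 2 * (probs[hi] - 0.5)

  num <- xq[hi] - A
  den <- A - xq[lo]
  valid <- num > 0 & den > 0
  if (!any(valid)) stop_degenerate("no valid symmetric percentile pairs")
  g <- weighted_median(log(num[valid] / den[valid]) / zp[valid], wp[valid])

  spread <- xq[hi] - xq[lo]
  yp <- if (abs(g) < .G_EPS) spread / (2 * zp)
        else g * spread / (exp(g * zp) - exp(-g * zp))
  vy <- yp > 0
  if (sum(vy) < 2L) stop_degenerate("not enough positive percentile spreads")
  u <- zp[vy]^2 / 2
  v <- log(yp[vy])
  wv <- wp[vy]
  ubar <- sum(wv * u) / sum(wv)
  vbar <- sum(wv * v) / sum(wv)
  h <- sum(wv * (u - ubar) * (v - vbar)) / sum(wv * (u - ubar)^2)
  lnB <- vbar - h * ubar

  if (shrinkage) {
    g <- (1 - shrink_g) * g
    h <- (1 - shrink_h) * h
  }
  h <- max(h, 0)
  tgh_params(A = A, B = exp(lnB), g = g, h = h)
}

#' Fit a Tukey g-and-h model from a single symmetric percentile pair
#'
#' The two-percentile baseline estimator: A is the median, g comes from the
#' single pair (p, 1 - p), and B and h are solved exactly from the two
#' equations log y_q = log B + h z_q^2 / 2 at q = p and q = 0.75.
#'
#' @param x numeric sample with distinct quartiles.
#' @param p upper percentile in (0.5, 1), conventionally 0.90-0.99.
#' @return a [tgh_params()] object.
#' @export
fit_tgh_two_percentile <- function(x, p = 0.9) {
  stopifnot(p > 0.5, p < 1)
  x <- x[is.finite(x)]
  if (length(x) < 4L) stop("fit_tgh_two_percentile: need at least 4 points")
  if (max(x) == min(x)) stop_degenerate("constant sample")
  A <- median(x)
  qs <- sample_quantile(x, c(1 - p, 0.25, 0.75, p))
  if (qs[3] <= qs[2]) stop_degenerate("quartiles are not distinct")
  num <- qs[4] - A
  den <- A - qs[1]
  if (num <= 0 || den <= 0) stop_degenerate("invalid half-spread ratio")
  zp <- qnorm(p)
  z75 <- qnorm(0.75)
  g <- log(num / den) / zp

  yq <- function(xu, xl, z) {
    if (abs(g) < .G_EPS) (xu - xl) / (2 * z)
    else g * (xu - xl) / (exp(g * z) - exp(-g * z))
  }
  yp <- yq(qs[4], qs[1], zp)
  y75 <- yq(qs[3], qs[2], z75)
  if (yp <= 0 || y75 <= 0) stop_degenerate("non-positive percentile spread")
  h <- (log(yp) - log(y75)) / ((zp^2 - z75^2) / 2)
  h <- max(h, 0)
  B <- exp(log(y75) - h * z75^2 / 2)
  tgh_params(A = A, B = B, g = g, h = h)
}
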