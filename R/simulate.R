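# Generators for the benchmark experiments: ten distribution families (ten
# parameter values each), the outlier-injection schemes, three diagnostic
# series (trimodal spacing, increasing skew, increasing monotonic
# distortion), and the multivariate cell-contamination scheme. All draws
# come from the caller's RNG stream (use set.seed for reproducibility).

# Per-family 10-point parameter grids. The benchmark prints grids only for
# the diagnostic series; these family grids are declared configuration
# spanning mild to extreme shapes.
family_grids <- function() {
  list(
    lognormal = seq(0.1, 1.0, length.out = 10),        # sdlog
    exponential = seq(1.1, 2.45, length.out = 10),     # Exp(1)^a power
    power = seq(0.5, 5, length.out = 10),              # density a x^(a-1)
    poisson = seq(2, 20, length.out = 10),             # lambda
    negative_binomial = seq(0.05, 0.5, length.out = 10), # success prob
    tukey_g = seq(0.075, 0.75, length.out = 10),       # g, h = 0
    tukey_h = seq(0.02, 0.2, length.out = 10),         # h, g = 0
    tukey_gh = seq(0.02, 0.2, length.out = 10),        # g = h
    beta = seq(0.5, 5, length.out = 10),               # beta, alpha = 2
    nonstandard = 1:10
  )
}

rtriangular <- function(n, a, b, c) {
  u <- runif(n)
  fc <- (c - a) / (b - a)
  ifelse(u < fc, a + sqrt(u * (b - a) * (c - a)),
         b - sqrt((1 - u) * (b - a) * (b - c)))
}

# Ten synthetic non-smooth and/or multimodal shapes: uniforms, triangulars,
# normal mixtures, and mixtures thereof (declared approximations).
nonstandard_sample <- function(shape, n) {
  pick <- function(...) {
    parts <- list(...)
    k <- sample.int(length(parts), n, replace = TRUE)
    out <- numeric(n)
    for (i in seq_along(parts)) {
      idx <- which(k == i)
      out[idx] <- parts[[i]](length(idx))
    }
    out
  }
  switch(shape,
    runif(n),                                             # 1 uniform
    runif(n, -5, 5),                                      # 2 wide uniform
    rtriangular(n, 0, 1, 0.5),                            # 3 symmetric triangular
    rtriangular(n, 0, 1, 0.05),                           # 4 skewed triangular
    pick(function(m) rnorm(m, -2), function(m) rnorm(m, 2)),   # 5 bimodal, close
    pick(function(m) rnorm(m, -6), function(m) rnorm(m, 6)),   # 6 bimodal, far
    pick(function(m) rnorm(m, -6), function(m) rnorm(m),
         function(m) rnorm(m, 6)),                             # 7 trimodal
    pick(function(m) runif(m, -1, 1), function(m) rnorm(m, 4)), # 8 uniform+normal
    pick(function(m) rnorm(m), function(m) runif(m, -8, 8)),    # 9 normal+uniform tails
    pick(function(m) rnorm(m, 0, 1), function(m) rnorm(m, 5, 0.5),
         function(m) runif(m, 8, 10)))                          # 10 mixed
}

#' Simulate one benchmark distribution
#'
#' Draws `n` points from one of the ten benchmark families at the
#' `param_index`-th value of its declared parameter grid (see
#' `ghoutliers:::family_grids()` for the grids).
#'
#' @param family one of `"lognormal"`, `"exponential"` (Exp(1) raised to a
#'   power), `"power"`, `"poisson"`, `"negative_binomial"`, `"tukey_g"`,
#'   `"tukey_h"`, `"tukey_gh"` (g = h), `"beta"` (alpha = 2), or
#'   `"nonstandard"`.
#' @param param_index grid position, 1-10.
#' @param n sample size (default 100000).
#' @return numeric vector of length `n`.
#' @export
#' @examples
#' set.seed(5)
#' mean(simulate_family("beta", 10, n = 1000)) # Beta(2, 5): mean 2/7
simulate_family <- function(family, param_index, n = 1e5) {
  grids <- family_grids()
  if (!family %in% names(grids)) {
    stop("simulate_family: unknown family '", family, "'")
  }
  stopifnot(param_index %in% 1:10)
  v <- grids[[family]][param_index]
  switch(family,
         lognormal = rlnorm(n, 0, v),
         exponential = rexp(n)^v,
         power = rbeta(n, v, 1),
         poisson = as.numeric(rpois(n, v)),
         negative_binomial = as.numeric(rnbinom(n, size = 10, prob = v)),
         tukey_g = tgh_sample(n, tgh_params(0, 1, g = v, h = 0)),
         tukey_h = tgh_sample(n, tgh_params(0, 1, g = 0, h = v)),
         tukey_gh = tgh_sample(n, tgh_params(0, 1, g = v, h = v)),
         beta = rbeta(n, 2, v),
         nonstandard = nonstandard_sample(v, n))
}

#' Inject ground-truth outliers into a sample
#'
#' Randomly replaces `n_out` points. One-sided outliers are drawn as
#' `p99.5 + eps`; two-sided injection converts half of the selected points
#' to `p99.75 + eps` and the other half to `p0.25 - eps` (the 0.25th
#' percentile, i.e. the far lower tail), with `eps ~ Uniform(0.5 s, 2 s)`
#' and `s` the standard deviation of the original sample. Quantiles and `s`
#' are computed before replacement.
#'
#' @param x numeric sample.
#' @param n_out number of points to replace (default 300; must be < n).
#' @param sided `"one"` or `"two"`.
#' @return a list of class `"contaminated_sample"`: `values`,
#'   `outlier_mask` (logical, `TRUE` at replaced positions), and `spec`.
#' @export
#' @examples
#' set.seed(6)
#' cs <- inject_outliers(rnorm(10000), n_out = 100, sided = "two")
#' sum(cs$outlier_mask)
inject_outliers <- function(x, n_out = 300, sided = c("two", "one")) {
  sided <- match.arg(sided)
  n <- length(x)
  if (n_out >= n) stop("inject_outliers: n_out must be smaller than n")
  s <- sd(x)
  values <- x
  mask <- rep(FALSE, n)
  if (n_out > 0) {
    idx <- sample.int(n, n_out)
    mask[idx] <- TRUE
    if (sided == "one") {
      anchor <- sample_quantile(x, 0.995)
      values[idx] <- anchor + runif(n_out, 0.5 * s, 2 * s)
    } else {
      n_up <- n_out %/% 2
      up <- idx[seq_len(n_up)]
      dn <- idx[(n_up + 1):n_out]
      values[up] <- sample_quantile(x, 0.9975) + runif(length(up), 0.5 * s, 2 * s)
      values[dn] <- sample_quantile(x, 0.0025) - runif(length(dn), 0.5 * s, 2 * s)
    }
  }
  structure(list(values = values, outlier_mask = mask,
                 spec = list(n = n, n_out = n_out, sided = sided, sd = s)),
            class = "contaminated_sample")
}

#' @export
print.contaminated_sample <- function(x, ...) {
  cat(sprintf("contaminated sample: n = %d, %d injected %s-sided outliers\n",
              x$spec$n, x$spec$n_out, x$spec$sided))
  invisible(x)
}

#' Diagnostic series: trimodal normal mixtures with growing mode spacing
#'
#' Equal-weight mixture of three unit-variance normals with adjacent means
#' separated by the `index`-th value of the 50-point grid from 5 to 33.
#'
#' @param index series position, 1-50 (1 -> spacing 5, 50 -> spacing 33).
#' @param n sample size.
#' @return numeric vector of length `n`.
#' @export
trimodal_series <- function(index, n = 1e5) {
  stopifnot(index %in% 1:50)
  spacing <- seq(5, 33, length.out = 50)[index]
  comp <- sample.int(3, n, replace = TRUE)
  rnorm(n, mean = (comp - 1) * spacing, sd = 1)
}

#' Diagnostic series: increasing Tukey-g skew
#'
#' Tukey g-and-h draws with `h = 0` and `g` on the 50-point grid
#' 0.015, 0.030, ..., 0.75.
#'
#' @param index series position, 1-50.
#' @param n sample size.
#' @return numeric vector of length `n`.
#' @export
skew_series <- function(index, n = 1e5) {
  stopifnot(index %in% 1:50)
  tgh_sample(n, tgh_params(0, 1, g = 0.015 * index, h = 0))
}

#' Diagnostic series: increasingly distorted monotonic distributions
#'
#' Standard exponential draws raised to the power `a` on the 50-point grid
#' 1.03, 1.06, ..., 2.5.
#'
#' @param index series position, 1-50.
#' @param n sample size.
#' @return numeric vector of length `n` (all nonnegative).
#' @export
monotonic_series <- function(index, n = 1e5) {
  stopifnot(index %in% 1:50)
  rexp(n)^(1 + 0.03 * index)
}

#' Multivariate cell-contamination scheme
#'
#' Simulates an `n x d` matrix from a standard normal or Uniform(-1, 1)
#' base, then replaces `fraction` of all scalar cells with sign-uniform
#' values whose magnitude is drawn from `[M, M + margin]`, `M = max(abs(D))`
#' over the clean matrix — every injected scalar is strictly more extreme
#' than every clean scalar.
#'
#' @param n rows (default 10000).
#' @param d columns (default 20).
#' @param base `"normal"` or `"uniform"`.
#' @param fraction fraction of cells replaced (default 0.01).
#' @param margin magnitude margin above `M` (default 0.5).
#' @return list with `matrix` and logical `cell_mask` of the same shape.
#' @export
multivariate_contaminate <- function(n = 1e4, d = 20,
                                     base = c("normal", "uniform"),
                                     fraction = 0.01, margin = 0.5) {
  base <- match.arg(base)
  stopifnot(fraction >= 0, fraction < 1)
  D <- matrix(if (base == "normal") rnorm(n * d) else runif(n * d, -1, 1),
              nrow = n, ncol = d)
  mask <- matrix(FALSE, n, d)
  n_cells <- round(fraction * n * d)
  if (n_cells > 0) {
    M <- max(abs(D))
    cells <- sample.int(n * d, n_cells)
    signs <- sample(c(-1, 1), n_cells, replace = TRUE)
    D[cells] <- signs * runif(n_cells, M, M + margin)
    mask[cells] <- TRUE
  }
  list(matrix = D, cell_mask = mask)
}
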