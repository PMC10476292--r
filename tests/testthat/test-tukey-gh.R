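test_that("the g-and-h transform matches closed forms and stays monotone", {
  expect_identical(tgh_transform(0, tgh_params(0, 1)), 0)
  expect_equal(tgh_transform(1.3, tgh_params(5, 2)), 7.6)
  # independent evaluation of the defining formula at g = 0.5, h = 0.1
  expect_equal(tgh_transform(1, tgh_params(0, 1, 0.5, 0.1)),
               ((exp(0.5) - 1) / 0.5) * exp(0.05), tolerance = 1e-12)
  # continuity across the g -> 0 branch switch
  z <- seq(-4, 4, 0.5)
  expect_equal(tgh_transform(z, tgh_params(0, 1, 1e-9, 0.1)),
               tgh_transform(z, tgh_params(0, 1, 0, 0.1)), tolerance = 1e-7)
  # strict monotonicity for h >= 0, any g
  set.seed(101)
  for (i in 1:20) {
    p <- tgh_params(rnorm(1), rexp(1) + 0.1, runif(1, -1, 1), runif(1, 0, 0.5))
    zz <- sort(runif(200, -8, 8))
    expect_true(all(diff(tgh_transform(zz, p)) > 0))
  }
})

test_that("quantile function passes through the normal quantile", {
  p <- tgh_params(3, 2, 0.4, 0.2)
  expect_equal(tgh_quantile(0.5, p), 3)
  expect_equal(tgh_quantile(0.75, tgh_params(0, 1)), qnorm(0.75))
  # closed form at a tabulated normal quantile, g only
  pr <- pnorm(3)
  expect_equal(tgh_quantile(pr, tgh_params(0, 1, 0.5, 0)),
               (exp(0.5 * 3) - 1) / 0.5, tolerance = 1e-12)
  expect_error(tgh_quantile(0, p), "strictly")
  expect_error(tgh_quantile(1.2, p), "strictly")
})

test_that("tgh_inverse round-trips the transform over random parameters", {
  expect_equal(tgh_inverse(5, tgh_params(5, 2, 0.3, 0.1)), 0)
  expect_equal(tgh_inverse(1.363964, tgh_params(0, 1, 0.5, 0.1)), 1,
               tolerance = 1e-5)
  set.seed(102)
  for (i in 1:25) {
    p <- tgh_params(rnorm(1), rexp(1) + 0.1, runif(1, -0.8, 0.8),
                    runif(1, 0, 0.4))
    z <- seq(-5, 5, length.out = 41)
    x <- tgh_transform(z, p)
    expect_equal(tgh_inverse(x, p, tol = 1e-12), z, tolerance = 1e-8)
  }
})

test_that("density matches the normal case, integrates to 1, and agrees with
          a finite-difference CDF oracle", {
  expect_equal(tgh_density(0, tgh_params(0, 1)), dnorm(0))
  set.seed(103)
  for (i in 1:5) {
    p <- tgh_params(rnorm(1), rexp(1) + 0.5, runif(1, -0.5, 0.5),
                    runif(1, 0, 0.3))
    lo <- tgh_quantile(1e-10, p)
    hi <- tgh_quantile(1 - 1e-10, p)
    total <- integrate(function(x) tgh_density(x, p), lo, hi,
                       rel.tol = 1e-8)$value
    expect_equal(total, 1, tolerance = 1e-3)
  }
  # finite-difference derivative of the numerically inverted CDF
  p <- tgh_params(0, 1, 0.3, 0.05)
  eps <- 1e-5
  fd <- (tgh_cdf(1 + eps, p) - tgh_cdf(1 - eps, p)) / (2 * eps)
  expect_equal(tgh_density(1, p), fd, tolerance = 1e-6)
  # zero density outside the bounded support (h = 0, g != 0)
  pb <- tgh_params(0, 1, -0.6, 0)
  expect_identical(tgh_density(10, pb), 0)
  expect_identical(tgh_cdf(10, pb), 1)
})

test_that("sampling is the transform of the generator's normal stream", {
  set.seed(104)
  draws <- tgh_sample(5, tgh_params(0, 1))
  set.seed(104)
  expect_identical(draws, rnorm(5))
  set.seed(105)
  x <- tgh_sample(1e5, tgh_params(0, 1))
  expect_lt(abs(median(x)), 0.02)
  set.seed(106)
  expect_equal(mean(tgh_sample(1e5, tgh_params(2, 3))), 2, tolerance = 0.05)
})

test_that("percentile regression recovers parameters from exact quantiles", {
  # exact standard-normal grid: g = h = 0 exactly before shrinkage
  f0 <- fit_tgh_percentile(qnorm((1:100 - 0.5) / 100), shrinkage = FALSE)
  expect_lt(abs(f0$g), 1e-9)
  expect_lt(abs(f0$h), 1e-9)
  expect_lt(abs(f0$A), 1e-9)
  # exact-quantile fixture (grid positions land on order statistics)
  f <- fit_tgh_percentile(tgh_quantile_fixture(tgh_params(0, 1, 0.3, 0.1)),
                          shrinkage = FALSE)
  expect_equal(c(f$A, f$B, f$g, f$h), c(0, 1, 0.3, 0.1), tolerance = 1e-9)
})

test_that("percentile regression recovers parameters from large samples and
          shrinkage only moves estimates toward zero", {
  set.seed(107)
  x <- tgh_sample(1e5, tgh_params(0, 1, 0.2, 0.05))
  f_on <- fit_tgh_percentile(x)
  f_off <- fit_tgh_percentile(x, shrinkage = FALSE)
  expect_gt(f_on$g, 0)
  expect_lte(f_on$g, abs(f_off$g))
  expect_lte(f_on$h, max(f_off$h, 0))
  expect_equal(f_off$g, 0.2, tolerance = 0.05)
  expect_equal(f_off$h, 0.05, tolerance = 0.03)
  expect_error(fit_tgh_percentile(rep(1, 200)), class = "ghoutliers_degenerate")
  expect_error(fit_tgh_percentile(rnorm(50)), "grid_size")
})

test_that("median absolute recovery error stays below 0.02 at n = 1e5", {
  set.seed(108)
  errs <- t(vapply(1:50, function(i) {
    g <- runif(1, 0, 0.5)
    h <- runif(1, 0, 0.2)
    x <- tgh_sample(1e5, tgh_params(0, 1, g, h))
    f <- fit_tgh_percentile(x, shrinkage = FALSE)
    c(abs(f$g - g), abs(f$h - h))
  }, numeric(2)))
  expect_lt(median(errs[, 1]), 0.02)
  expect_lt(median(errs[, 2]), 0.02)
})

test_that("two-percentile estimator solves the two-equation system exactly", {
  fn <- fit_tgh_two_percentile(quantile_fixture(qnorm), p = 0.99)
  expect_equal(c(fn$A, fn$B, fn$g, fn$h), c(0, 1, 0, 0), tolerance = 1e-9)
  fg <- fit_tgh_two_percentile(tgh_quantile_fixture(tgh_params(0, 1, 0.4, 0)),
                               p = 0.95)
  expect_equal(fg$g, 0.4, tolerance = 1e-9)
  expect_lt(fg$h, 1e-9)
  expect_error(fit_tgh_two_percentile(rep(2, 100)),
               class = "ghoutliers_degenerate")
})
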