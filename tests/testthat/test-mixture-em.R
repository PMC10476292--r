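test_that("E step matches the closed-form normal-mixture responsibility", {
  m <- ghoutliers:::new_mixture(c(0.3, 0.7),
                                list(tgh_params(-2, 1), tgh_params(2, 1)))
  z <- c(-1.5, 0.2)
  r <- e_step(z, m)
  closed <- 0.3 * dnorm(z, -2) / (0.3 * dnorm(z, -2) + 0.7 * dnorm(z, 2))
  expect_equal(r[, 1], closed, tolerance = 1e-9)
  expect_equal(rowSums(r), c(1, 1))
  # identical components: responsibilities collapse to the weights
  mi <- ghoutliers:::new_mixture(c(0.4, 0.6),
                                 list(tgh_params(0, 1), tgh_params(0, 1)))
  ri <- e_step(rnorm(10), mi)
  expect_true(all(abs(ri[, 1] - 0.4) < 1e-12))
  # dominance near a far-away component's location
  rd <- e_step(-2, m)
  expect_gt(rd[1, 1], 0.999)
})

test_that("stochastic M step concentrates weights and collapses on
          degenerate responsibilities", {
  set.seed(501)
  z <- c(rnorm(5e4, -3), rnorm(5e4, 3))
  r <- cbind(rep(0.5, 1e5), rep(0.5, 1e5))
  m <- m_step(z, r)
  expect_equal(m$weights[1], 0.5, tolerance = 0.01)
  r1 <- cbind(rep(1, 1e3), rep(0, 1e3))
  expect_error(m_step(rnorm(1e3), r1), class = "ghoutliers_collapse")
})

test_that("EM recovers a well-separated two-component mixture", {
  set.seed(502)
  z <- c(rnorm(25000, -3), rnorm(25000, 3))
  m <- fit_mixture(z, seed = 502)
  expect_equal(m$components[[1]]$A, -3, tolerance = 0.2)
  expect_equal(m$components[[2]]$A, 3, tolerance = 0.2)
  expect_equal(m$weights[1], 0.5, tolerance = 0.03)
  expect_lte(m$components[[1]]$A, m$components[[2]]$A) # ordered by location
})

test_that("stochastic and responsibility-weighted M steps agree at large n", {
  diffs <- t(vapply(1:10, function(s) {
    set.seed(600 + s)
    z <- c(rnorm(25000, -3), rnorm(25000, 3))
    ms <- fit_mixture(z, seed = 600 + s)
    mw <- fit_mixture(z, stochastic = FALSE, seed = 600 + s)
    unlist(lapply(1:2, function(k) {
      a <- ms$components[[k]]; b <- mw$components[[k]]
      c(abs(a$A - b$A), abs(a$B - b$B), abs(a$g - b$g), abs(a$h - b$h))
    }))
  }, numeric(8)))
  expect_lt(max(diffs[, c(1, 2, 5, 6)]), 0.1)  # A, B
  expect_lt(max(diffs[, c(3, 4, 7, 8)]), 0.05) # g, h
})

test_that("EM on unimodal input keeps downstream cutoffs close to the
          single-model fit", {
  set.seed(503)
  z <- rnorm(2e4)
  mix <- fit_mixture(z, seed = 503, max_iter = 30)
  single <- fit_tgh_percentile(z)
  a <- 0.0035
  cm <- ghoutliers:::mixture_quantile(c(a, 1 - a), mix)
  cs <- tgh_quantile(c(a, 1 - a), single)
  # computed agreement of the 99.3% coverage cuts on this simulation: the
  # spurious low-weight component can stretch one cut by several percent
  expect_lt(max(abs(cm - cs) / abs(cs)), 0.15)
})

test_that("max_iter = 0 returns the initialization model", {
  set.seed(504)
  z <- c(rnorm(500, -4), rnorm(500, 4))
  m0 <- fit_mixture(z, max_iter = 0, seed = 504)
  expect_equal(m0$n_iter, 0L)
  expect_lt(m0$components[[1]]$A, 0)
  expect_gt(m0$components[[2]]$A, 0)
})

test_that("mixture CDF is a proper monotone mixture of component CDFs", {
  m <- ghoutliers:::new_mixture(c(0.25, 0.75),
                                list(tgh_params(-2, 1, 0.1, 0.05),
                                     tgh_params(3, 2, -0.2, 0.1)))
  z <- seq(-10, 15, length.out = 50)
  cdf <- mixture_cdf(z, m)
  expect_true(all(diff(cdf) >= 0))
  expect_equal(mixture_cdf(ghoutliers:::mixture_quantile(0.37, m), m), 0.37,
               tolerance = 1e-8)
})
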