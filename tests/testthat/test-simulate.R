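test_that("family generators produce the declared shapes", {
  set.seed(801)
  expect_gt(mean((function(x) mean((x - mean(x))^3))(
    simulate_family("tukey_g", 4, 2e4))), 0) # positive g skews right
  pois <- simulate_family("poisson", 5, 5e3)
  expect_true(all(pois >= 0 & pois == round(pois)))
  nb <- simulate_family("negative_binomial", 3, 5e3)
  expect_true(all(nb >= 0 & nb == round(nb)))
  # closed-form Beta(2, 5) mean with a CLT tolerance
  expect_equal(mean(simulate_family("beta", 10, 1e5)), 2 / 7,
               tolerance = 0.005 * 7 / 2)
  expect_true(all(simulate_family("power", 2, 1e3) >= 0))
  expect_error(simulate_family("cauchy", 1), "unknown family")
  for (i in 1:10) {
    expect_length(simulate_family("nonstandard", i, 500), 500)
  }
})

test_that("one-sided injection lands in the stated interval", {
  set.seed(802)
  x <- rnorm(1e5)
  s <- sd(x)
  anchor <- unname(quantile(x, 0.995, type = 7))
  cs <- inject_outliers(x, 300, "one")
  inj <- cs$values[cs$outlier_mask]
  expect_length(inj, 300)
  expect_true(all(inj >= anchor + 0.5 * s & inj <= anchor + 2 * s))
  expect_identical(cs$values[!cs$outlier_mask], x[!cs$outlier_mask])
})

test_that("two-sided injection splits half and half around the anchors", {
  set.seed(803)
  x <- rlnorm(5e4)
  s <- sd(x)
  up_anchor <- unname(quantile(x, 0.9975, type = 7))
  dn_anchor <- unname(quantile(x, 0.0025, type = 7))
  cs <- inject_outliers(x, 300, "two")
  inj <- cs$values[cs$outlier_mask]
  n_up <- sum(inj > up_anchor)
  n_dn <- sum(inj < dn_anchor)
  expect_equal(n_up, 150)
  expect_equal(n_dn, 150)
  expect_true(all(inj[inj > up_anchor] <= up_anchor + 2 * s))
  expect_true(all(inj[inj < dn_anchor] >= dn_anchor - 2 * s))
  cs0 <- inject_outliers(x, 0)
  expect_identical(cs0$values, x)
  expect_false(any(cs0$outlier_mask))
  expect_error(inject_outliers(1:10, 10), "smaller")
})

test_that("diagnostic series follow the printed parameter grids", {
  grid <- seq(5, 33, length.out = 50)
  expect_equal(grid[1], 5)
  expect_equal(grid[50], 33)
  set.seed(804)
  x <- trimodal_series(50, 3e4)
  km <- kmeans(x, centers = c(0, 33, 66))
  expect_equal(as.numeric(table(km$cluster)) / 3e4, rep(1 / 3, 3),
               tolerance = 0.05) # ~n/3 per component
  expect_equal(unname(sort(km$centers[, 1])), c(0, 33, 66), tolerance = 0.05)
  # skew grid: 0.015 * index; monotonic grid: 1 + 0.03 * index
  set.seed(805)
  m1 <- monotonic_series(1, 1e3)
  expect_true(all(m1 >= 0))
  expect_error(skew_series(51), "1:50")
  s50 <- skew_series(50, 2e4)
  s1 <- skew_series(1, 2e4)
  sk <- function(v) mean((v - mean(v))^3) / sd(v)^3
  expect_gt(sk(s50), sk(s1)) # skew grows along the grid
})

test_that("multivariate contamination makes every injected cell the most
          extreme in the matrix", {
  set.seed(806)
  for (base in c("normal", "uniform")) {
    mc <- multivariate_contaminate(2000, 20, base)
    expect_equal(sum(mc$cell_mask), round(0.01 * 2000 * 20))
    expect_gt(min(abs(mc$matrix[mc$cell_mask])),
              max(abs(mc$matrix[!mc$cell_mask])))
  }
  mc0 <- multivariate_contaminate(500, 20, "normal", fraction = 0)
  expect_false(any(mc0$cell_mask))
})

test_that("generators are reproducible under a fixed seed", {
  set.seed(807)
  a <- simulate_family("lognormal", 3, 1000)
  set.seed(807)
  b <- simulate_family("lognormal", 3, 1000)
  expect_identical(a, b)
  set.seed(808)
  c1 <- inject_outliers(rnorm(2000), 50)
  set.seed(808)
  c2 <- inject_outliers(rnorm(2000), 50)
  expect_identical(c1$values, c2$values)
})
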