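# Bimodal Tukey g-and-h mixture fitted to probit scores by stochastic EM:
# the E step computes component responsibilities from the current densities;
# the M step draws hard assignments from the responsibilities and refits
# each component by percentile regression (with shrinkage on, as in the
# single-model fit). With growing n the stochastic M step approaches the
# responsibility-weighted (standard EM) M step, which is also provided.

new_mixture <- function(weights, components, loglik = NA_real_,
                        n_iter = 0L, collapsed = FALSE) {
  o <- order(vapply(components, `[[`, numeric(1), "A"))
  structure(list(weights = weights[o], components = components[o],
                 loglik = loglik, n_iter = n_iter, collapsed = collapsed),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("bimodal Tukey g-and-h mixture%s (mean loglik %.5g, %d iterations)\n",
              if (x$collapsed) " [collapsed to a single component]" else "",
              x$loglik, x$n_iter))
  for (k in 1:2) {
    p <- x$components[[k]]
    cat(sprintf("  pi%d = %.3f: A = %.4g, B = %.4g, g = %.4g, h = %.4g\n",
                k, x$weights[k], p$A, p$B, p$g, p$h))
  }
  invisible(x)
}

# Per-point per-component log densities (n x 2).
mixture_logdens <- function(z, model) {
  cbind(log(model$weights[1]) + tgh_density(z, model$components[[1]], log = TRUE),
        log(model$weights[2]) + tgh_density(z, model$components[[2]], log = TRUE))
}

# Mean log-likelihood under the mixture.
mixture_mean_loglik <- function(z, model) {
  ld <- mixture_logdens(z, model)
  m <- pmax(ld[, 1], ld[, 2])
  mean(m + log(exp(ld[, 1] - m) + exp(ld[, 2] - m)))
}

#' Mixture cumulative distribution function
#'
#' @param z numeric vector on the model (probit) scale.
#' @param model a `"mixture_model"` from [fit_mixture()].
#' @return numeric vector of probabilities.
#' @export
mixture_cdf <- function(z, model) {
  model$weights[1] * tgh_cdf(z, model$components[[1]]) +
    model$weights[2] * tgh_cdf(z, model$components[[2]])
}

# Quantile of the mixture by monotone root search.
mixture_quantile <- function(p, model) {
  vapply(p, function(pp) {
    lo <- min(tgh_quantile(1e-9, model$components[[1]]),
              tgh_quantile(1e-9, model$components[[2]]))
    hi <- max(tgh_quantile(1 - 1e-9, model$components[[1]]),
              tgh_quantile(1 - 1e-9, model$components[[2]]))
    uniroot(function(q) mixture_cdf(q, model) - pp, c(lo, hi),
            extendInt = "upX", tol = 1e-10)$root
  }, numeric(1))
}

#' E step: component responsibilities
#'
#' `r_ik = pi_k f_k(z_i) / sum_j pi_j f_j(z_i)` with `f_k` the component
#' g-and-h densities, computed in log space; points where both densities
#' underflow get (0.5, 0.5).
#'
#' @param z probit scores.
#' @param model a `"mixture_model"`.
#' @return an n x 2 matrix of responsibilities, rows summing to 1.
#' @export
e_step <- function(z, model) {
  ld <- mixture_logdens(z, model)
  m <- pmax(ld[, 1], ld[, 2])
  both_zero <- !is.finite(m)
  r1 <- exp(ld[, 1] - m) / (exp(ld[, 1] - m) + exp(ld[, 2] - m))
  if (any(both_zero)) {
    warning("e_step: points with zero density under both components")
    r1[both_zero] <- 0.5
  }
  cbind(r1, 1 - r1)
}

#' M step: stochastic assignment and percentile refit
#'
#' Draws hard component assignments from the responsibilities, re-estimates
#' the mixing weights as assigned fractions, and refits each component with
#' [fit_tgh_percentile()] (shrinkage on). Draws are retried when a component
#' receives fewer than `min_component_points`; exceeding `max_retry` raises
#' a component-collapse error.
#'
#' @param z probit scores.
#' @param r responsibility matrix from [e_step()].
#' @param min_component_points minimum points per component (default 100).
#' @param max_retry assignment retries before collapse (default 10).
#' @param grid_size percentile grid for the component fits.
#' @return a `"mixture_model"`.
#' @export
m_step <- function(z, r, min_component_points = 100, max_retry = 10,
                   grid_size = 100) {
  n <- length(z)
  for (try in seq_len(max_retry + 1L)) {
    a <- rbinom(n, 1L, r[, 1]) == 1L
    n1 <- sum(a)
    if (n1 >= min_component_points && n - n1 >= min_component_points) {
      f1 <- fit_tgh_percentile(z[a], grid_size = min(grid_size, n1))
      f2 <- fit_tgh_percentile(z[!a], grid_size = min(grid_size, n - n1))
      return(new_mixture(c(n1, n - n1) / n, list(f1, f2)))
    }
  }
  stop(errorCondition("m_step: component collapsed (too few assigned points)",
                      class = c("ghoutliers_collapse", "error")))
}

# Responsibility-weighted (standard EM) M step: weighted percentile fits.
m_step_weighted <- function(z, r, grid_size = 100) {
  f1 <- fit_tgh_percentile(z, grid_size = grid_size, w = r[, 1])
  f2 <- fit_tgh_percentile(z, grid_size = grid_size, w = r[, 2])
  new_mixture(colMeans(r), list(f1, f2))
}

# Initial model: split z at the midpoint between the two tallest histogram
# peaks (fallback: the median) and fit each half.
mixture_init <- function(z, grid_size = 100, min_component_points = 100) {
  n <- length(z)
  br <- seq(min(z), max(z), length.out = 51L)
  cnt <- tabulate(findInterval(z, br, rightmost.closed = TRUE), 50L)
  mids <- (br[-1] + br[-51]) / 2
  is_peak <- vapply(seq_along(cnt), function(i) {
    l <- if (i > 1) cnt[i - 1] else -1
    r <- if (i < 50) cnt[i + 1] else -1
    cnt[i] > 0 && cnt[i] >= l && cnt[i] >= r
  }, logical(1))
  pk <- which(is_peak)[order(cnt[is_peak], decreasing = TRUE)]
  split <- if (length(pk) >= 2L) mean(mids[sort(pk[1:2])]) else median(z)
  lo <- z[z <= split]; hi <- z[z > split]
  if (length(lo) < min_component_points || length(hi) < min_component_points) {
    split <- median(z)
    lo <- z[z <= split]; hi <- z[z > split]
  }
  if (length(lo) < min_component_points || length(hi) < min_component_points) {
    stop(errorCondition("mixture_init: cannot form two components",
                        class = c("ghoutliers_collapse", "error")))
  }
  f1 <- fit_tgh_percentile(lo, grid_size = min(grid_size, length(lo)))
  f2 <- fit_tgh_percentile(hi, grid_size = min(grid_size, length(hi)))
  new_mixture(c(length(lo), length(hi)) / n, list(f1, f2))
}

#' Fit a bimodal Tukey g-and-h mixture by (stochastic) EM
#'
#' Alternates [e_step()] and [m_step()] from a histogram-peak initialization
#' until the relative change in mean log-likelihood stays below `tol` for 3
#' consecutive iterations or `max_iter` is reached, and returns the highest-
#' likelihood model seen. If a component collapses, the fit falls back to a
#' single percentile-regression model (returned as a mixture with weights
#' (1, 0) and `collapsed = TRUE`).
#'
#' @param z probit scores (length at least `2 * min_component_points`).
#' @param max_iter maximum EM iterations (default 100).
#' @param tol relative mean log-likelihood tolerance (default 1e-4).
#' @param min_component_points,grid_size see [m_step()].
#' @param stochastic logical; `FALSE` uses the responsibility-weighted
#'   (standard EM) M step instead of stochastic assignment.
#' @param seed optional integer seed for the stochastic assignments.
#' @return a `"mixture_model"`.
#' @export
#' @examples
#' set.seed(3)
#' z <- c(rnorm(2000, -3), rnorm(2000, 3))
#' fit_mixture(z, max_iter = 20, seed = 3)
fit_mixture <- function(z, max_iter = 100, tol = 1e-4,
                        min_component_points = 100, grid_size = 100,
                        stochastic = TRUE, seed = NULL) {
  if (length(z) < 2 * min_component_points) {
    stop("fit_mixture: too few points for two components")
  }
  with_seed(seed, {
    single_fallback <- function() {
      f <- fit_tgh_percentile(z, grid_size = min(grid_size, length(z)))
      m <- new_mixture(c(1, 0), list(f, f), collapsed = TRUE)
      m$loglik <- mean(tgh_density(z, f, log = TRUE))
      m
    }
    model <- tryCatch(mixture_init(z, grid_size, min_component_points),
                      ghoutliers_collapse = function(e) NULL)
    if (is.null(model)) return(single_fallback())
    model$loglik <- mixture_mean_loglik(z, model)
    best <- model
    prev_ll <- model$loglik
    consec <- 0L
    iter <- 0L
    while (iter < max_iter) {
      iter <- iter + 1L
      r <- e_step(z, model)
      model <- tryCatch(
        if (stochastic) m_step(z, r, min_component_points,
                               grid_size = grid_size)
        else m_step_weighted(z, r, grid_size = grid_size),
        ghoutliers_collapse = function(e) NULL)
      if (is.null(model)) return(single_fallback())
      ll <- mixture_mean_loglik(z, model)
      model$loglik <- ll
      model$n_iter <- iter
      if (ll > best$loglik) best <- model
      consec <- if (abs(ll - prev_ll) / (abs(prev_ll) + 1e-12) < tol)
        consec + 1L else 0L
      prev_ll <- ll
      if (consec >= 3L) break
    }
    best
  })
}
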