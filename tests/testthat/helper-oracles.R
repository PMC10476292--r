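# Independent oracles and fixture builders used across the test files.

# Exhaustive dip oracle for small n: minimize d over unimodal CDFs that
# thread the ECDF corridor, enumerating the mode over the unique data points
# (a unimodal CDF is continuous except possibly for an atom at its mode, so
# each candidate mode carries a free left-limit value). Feasibility of a
# candidate (mode, d) is a linear system checked with quadprog; the dip is
# found by bisection on d.
dip_oracle_feasible <- function(v, Fv, Fm, j, d) {
  k <- length(v)
  nv <- k + 1L # g_1..g_k, gL (left limit at the mode)
  iL <- k + 1L
  rows <- list(); rhs <- c()
  add <- function(r, b) {
    rows[[length(rows) + 1L]] <<- r
    rhs[length(rhs) + 1L] <<- b
  }
  for (i in 1:k) {
    lo <- Fv[i] - d
    hi <- if (i == j) Fv[i] + d else Fm[i] + d
    r <- numeric(nv); r[i] <- 1; add(r, max(lo, 0))
    r <- numeric(nv); r[i] <- -1; add(r, -min(hi, 1))
  }
  r <- numeric(nv); r[iL] <- 1; add(r, max(Fm[j] - d, 0))
  r <- numeric(nv); r[iL] <- -1; add(r, -min(Fm[j] + d, 1))
  for (i in seq_len(k - 1)) {
    if (i == j - 1 || i == j) next
    r <- numeric(nv); r[i] <- -1; r[i + 1] <- 1; add(r, 0)
  }
  if (j > 1) { r <- numeric(nv); r[j - 1] <- -1; r[iL] <- 1; add(r, 0) }
  r <- numeric(nv); r[iL] <- -1; r[j] <- 1; add(r, 0)
  vi <- function(i) if (i == j) iL else i
  if (j >= 3) for (i in 1:(j - 2)) { # convexity left of the mode
    d21 <- v[i + 2] - v[i + 1]; d10 <- v[i + 1] - v[i]
    r <- numeric(nv)
    r[vi(i)] <- r[vi(i)] + d21
    r[vi(i + 1)] <- r[vi(i + 1)] - (d21 + d10)
    r[vi(i + 2)] <- r[vi(i + 2)] + d10
    add(r, 0)
  }
  if (k - j >= 2) for (i in j:(k - 2)) { # concavity right of the mode
    d21 <- v[i + 2] - v[i + 1]; d10 <- v[i + 1] - v[i]
    r <- numeric(nv)
    r[i] <- r[i] - d21
    r[i + 1] <- r[i + 1] + (d21 + d10)
    r[i + 2] <- r[i + 2] - d10
    add(r, 0)
  }
  tryCatch({
    quadprog::solve.QP(Dmat = diag(nv), dvec = rep(0, nv),
                       Amat = t(do.call(rbind, rows)), bvec = rhs - 1e-11)
    TRUE
  }, error = function(e) FALSE)
}

dip_oracle <- function(x, tol = 1e-11) {
  x <- sort(x)
  v <- unique(x)
  k <- length(v)
  n <- length(x)
  if (k == 1) return(0)
  cnt <- cumsum(tabulate(match(x, v), k))
  Fv <- cnt / n
  Fm <- c(0, cnt[-k]) / n
  best <- Inf
  for (j in 1:k) {
    lo <- 0; hi <- 0.5
    if (!dip_oracle_feasible(v, Fv, Fm, j, hi)) next
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (dip_oracle_feasible(v, Fv, Fm, j, mid)) hi <- mid else lo <- mid
    }
    best <- min(best, hi)
  }
  best
}

# 201-point fixture of exact theoretical quantiles: values at probabilities
# (j-1)/200 for j = 2..200 plus finite stand-ins for the endpoint order
# statistics (which no percentile-grid or quartile position touches under
# the linear-interpolation convention). Sample quantiles at the (i-0.5)/100
# grid, the quartiles, and the median of this fixture equal the theoretical
# quantiles exactly, so estimator examples can be checked near machine
# precision.
tgh_quantile_fixture <- function(params) {
  tgh_quantile(c(0.001, (1:199) / 200, 0.999), params)
}

quantile_fixture <- function(qfun) {
  qfun(c(0.001, (1:199) / 200, 0.999))
}
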