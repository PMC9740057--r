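# Independent oracles used across the suite.  These deliberately avoid the
# package's own fitting code paths: grids + 1-D polish for nonlinear least
# squares, flood fill for connectivity, and direct enumeration for summary
# statistics.

spgr_signal <- function(t1, m0, tr, angles_deg) {
  a <- angles_deg * pi / 180
  e1 <- exp(-tr / t1)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

# Brute-force least-squares T1: dense grid with M0 profiled out in closed
# form, then a 1-D polish around the grid optimum.
oracle_t1 <- function(signals, angles_deg, tr,
                      grid = seq(50, 5000, by = 1)) {
  unit <- function(t1) spgr_signal(t1, 1, tr, angles_deg)
  score <- function(t1) {   # negative explained sum of squares
    f <- unit(t1)
    -sum(signals * f)^2 / sum(f * f)
  }
  g <- vapply(grid, score, numeric(1))
  t1g <- grid[which.min(g)]
  stats::optimize(score, c(t1g - 2, t1g + 2), tol = 1e-7)$minimum
}

# Brute-force least-squares mono-exponential decay rate (T2 or 1/ADC
# analogue): grid + polish on the *linear-scale* residuals, independent of
# the package's log-linear estimator.
oracle_decay <- function(signals, x, grid) {
  score <- function(tau) {
    f <- exp(-x / tau)
    -sum(signals * f)^2 / sum(f * f)
  }
  g <- vapply(grid, score, numeric(1))
  t0 <- grid[which.min(g)]
  step <- diff(grid[1:2])
  stats::optimize(score, c(t0 - step, t0 + step), tol = 1e-9)$minimum
}

# 6-connectivity flood fill.
shift3 <- function(m, ax, by) {
  d <- dim(m)
  out <- array(FALSE, d)
  src <- dst <- lapply(d, seq_len)
  if (by > 0) { dst[[ax]] <- (1 + by):d[ax]; src[[ax]] <- 1:(d[ax] - by) }
  else        { dst[[ax]] <- 1:(d[ax] + by); src[[ax]] <- (1 - by):d[ax] }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

is_connected_3d <- function(mask) {
  if (!any(mask)) return(FALSE)
  seed <- array(FALSE, dim(mask))
  seed[which(mask)[1]] <- TRUE
  repeat {
    grown <- (seed | shift3(seed, 1, 1) | shift3(seed, 1, -1) |
                shift3(seed, 2, 1) | shift3(seed, 2, -1) |
                shift3(seed, 3, 1) | shift3(seed, 3, -1)) & mask
    if (identical(grown, seed)) break
    seed <- grown
  }
  all(seed == mask)
}

# Dense-grid trapezoid as an independent numeric integral.
dense_integral <- function(f, upper, n = 200000) {
  tt <- seq(0, upper, length.out = n)
  y <- f(tt)
  sum(diff(tt) * (head(y, -1) + tail(y, -1)) / 2)
}

# A tiny noiseless phantom shared by several files.
tiny_phantom <- function(preset = "extracranial_pre", dims = c(24, 24, 12)) {
  build_phantom(dims, preset)
}
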