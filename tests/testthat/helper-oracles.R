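# Independent oracles used to cross-check the implementation. These share no
# code path with the package internals: the dense-grid search solves the
# normal equations in closed form (Cramer), and the running-mean oracle is a
# direct double loop.

# Dense-grid profiled least squares: for each candidate period solve
# y ~ 1 + sin + cos via explicit 3x3 normal equations and return the
# SSE-minimising period. Vectorised over the period grid.
oracle_dense_grid <- function(t, y, periods) {
  S <- sin(outer(t, 2 * pi / periods))
  C <- cos(outer(t, 2 * pi / periods))
  n <- length(t)
  ss <- colSums(S * S); cc <- colSums(C * C); sc <- colSums(S * C)
  s1 <- colSums(S); c1 <- colSums(C)
  sy <- colSums(S * y); cy <- colSums(C * y)
  y1 <- sum(y); yy <- sum(y * y)
  det3 <- n * (ss * cc - sc * sc) - s1 * (s1 * cc - sc * c1) +
    c1 * (s1 * sc - ss * c1)
  d0 <- y1 * (ss * cc - sc * sc) - s1 * (sy * cc - sc * cy) +
    c1 * (sy * sc - ss * cy)
  d1 <- n * (sy * cc - sc * cy) - y1 * (s1 * cc - sc * c1) +
    c1 * (s1 * cy - sy * c1)
  d2 <- n * (ss * cy - sy * sc) - s1 * (s1 * cy - sy * c1) +
    y1 * (s1 * sc - ss * c1)
  c0 <- d0 / det3; a <- d1 / det3; b <- d2 / det3
  sse <- yy - (c0 * y1 + a * sy + b * cy)
  k <- which.min(sse)
  list(period = periods[k], sse = sse[k], all_sse = sse)
}

# Direct-summation centered running mean with half-weights at the window
# ends (span = s intervals, s even); NA outside the valid region.
oracle_running_mean <- function(x, s) {
  n <- length(x)
  h <- s %/% 2L
  out <- rep(NA_real_, n)
  for (i in seq.int(h + 1L, n - h)) {
    acc <- 0.5 * x[i - h] + 0.5 * x[i + h]
    for (j in seq.int(i - h + 1L, i + h - 1L)) acc <- acc + x[j]
    out[i] <- acc / s
  }
  out
}

# OLS at fixed period via explicit normal equations (solve(crossprod)).
oracle_ols_sse <- function(t, y, period_h) {
  X <- cbind(1, sin(2 * pi * t / period_h), cos(2 * pi * t / period_h))
  beta <- solve(crossprod(X), crossprod(X, y))
  sum((y - X %*% beta)^2)
}

# A deterministic, fully parameter-free synthetic trace.
make_sine_trace <- function(period = 24, amp = 5, level = 0, phase = 0,
                            t = seq(0, 72, by = 0.2), well = "A1") {
  luminescenceTrace(well, t, level + amp * sin(2 * pi * (t - phase) / period))
}

# Noise-free, undamped, drift-free variant of a preset: the deterministic
# limit in which the fitted model is exact.
deterministic_preset <- function(name, n_wells, seed, ...) {
  scenarioPreset(name, n_wells = n_wells, seed = seed, noise_sd = 0,
                 damping_per_h = 0, baseline_decay_per_h = 0,
                 phase_jitter_sd_h = 0,
                 phase_diffusion_sd_h_per_sqrt_h = 0, ...)
}
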