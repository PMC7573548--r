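t_grid <- seq(0, 72, by = 0.2)

test_that("the fixed-period subproblem is solved exactly when nested", {
  tr <- luminescenceTrace("A1", t_grid, 7 + 3 * sin(2 * pi * t_grid / 24))
  f <- fitFixedPeriod(tr, 24)
  expect_equal(f$constant_level, 7, tolerance = 1e-10)
  expect_equal(f$amplitude, 3, tolerance = 1e-10)
  expect_lt(f$sse, 1e-18)
})

test_that("phase is the first ascending zero-crossing after t = 0", {
  # cos = sin shifted by +T/4, so its ascending zero sits at t = 18
  tr <- luminescenceTrace("A1", t_grid, 3 * cos(2 * pi * t_grid / 24))
  f <- fitFixedPeriod(tr, 24)
  expect_equal(f$amplitude, 3, tolerance = 1e-10)
  expect_equal(f$phase_h, 18, tolerance = 1e-9)

  # verify numerically: the fitted curve crosses zero upward at phase_h
  curve <- function(t) f$a * sin(2 * pi * t / 24) + f$b * cos(2 * pi * t / 24)
  expect_lt(abs(curve(f$phase_h)), 1e-9)
  expect_gt(curve(f$phase_h + 0.01) - curve(f$phase_h - 0.01), 0)

  # general phases round-trip through the convention
  for (ph in c(0.3, 7.9, 15.5, 23.2)) {
    fp <- fitFixedPeriod(make_sine_trace(period = 24, phase = ph), 24)
    expect_equal(fp$phase_h, ph, tolerance = 1e-6)
  }
})

test_that("least squares agrees with an independent normal-equations solve", {
  y <- withr::with_seed(11L, rnorm(361))
  tr <- luminescenceTrace("A1", t_grid, y)
  f <- fitFixedPeriod(tr, 24)
  expect_lt(abs(f$sse - oracle_ols_sse(t_grid, y, 24)), 1e-9)
  expect_lt(f$amplitude, 0.5)
})

test_that("aliasing-degenerate periods raise rather than fit silently", {
  tr <- luminescenceTrace("A1", t_grid, rnorm(361))
  expect_error(fitFixedPeriod(tr, 0.2), "rank-deficient")
})

test_that("a noiseless sinusoid is recovered exactly", {
  f <- fitSinusoid(make_sine_trace(period = 24, amp = 5))
  expect_lt(abs(periodHours(f) - 24), 0.001)
  expect_lt(abs(amplitude(f) - 5), 0.001)
  expect_gte(rSquared(f), 0.999)
  expect_true(isConverged(f))
  expect_false(isDegenerate(f))
})

test_that("constant input yields a degenerate fit, not an error", {
  f <- fitSinusoid(luminescenceTrace("A1", t_grid, rep(100, 361)))
  expect_true(isDegenerate(f))
  expect_identical(rSquared(f), 0)
  expect_identical(amplitude(f), 0)
  expect_identical(rhythmicityScore(f), 0)
})

test_that("the two-stage search matches a dense-grid oracle", {
  t <- seq(0, 36, by = 0.2)   # n = 181
  grid <- seq(16, 40, by = 0.001)
  set.seed(20)
  for (i in 1:10) {
    y <- rnorm(1, 50, 20) +
      rexp(1, 1 / 3) * sin(2 * pi * (t - runif(1, 0, 24)) / runif(1, 20, 32)) +
      rnorm(length(t), 0, 1)
    fit <- fitSinusoid(luminescenceTrace("A1", t, y))
    or <- oracle_dense_grid(t, y, grid)
    expect_lt(abs(fit@sse - or$sse) / or$sse, 1e-6)
    expect_lt(abs(periodHours(fit) - or$period), 0.005)
  }
})

test_that("fits are scale-equivariant and time-shift covariant", {
  y <- traceSignal(simulateTrace(simulationParams(
    period_h = 25.4, noise_sd = 10, seed = 8)))
  base <- fitSinusoid(luminescenceTrace("A1", t_grid, y))

  scaled <- fitSinusoid(luminescenceTrace("A1", t_grid, 3.7 * y + 250))
  expect_lt(abs(periodHours(scaled) - periodHours(base)), 1e-6)
  expect_lt(abs(phaseHours(scaled) - phaseHours(base)), 1e-6)
  expect_lt(abs(rSquared(scaled) - rSquared(base)), 1e-6)
  expect_lt(abs(amplitude(scaled) - 3.7 * amplitude(base)),
            1e-6 * amplitude(base))

  # shifting the time axis by +delta moves the signal earlier relative to
  # t = 0, so the phase shifts by -delta (mod T)
  delta <- 5.3
  shifted <- fitSinusoid(luminescenceTrace("A1", t_grid - delta, y))
  expect_lt(abs(periodHours(shifted) - periodHours(base)), 5e-3)
  expect_lt(abs(amplitude(shifted) / amplitude(base) - 1), 1e-3)
  expect_lt(abs(rSquared(shifted) - rSquared(base)), 1e-4)
  d <- (phaseHours(base) - delta - phaseHours(shifted)) %% periodHours(base)
  expect_lt(min(d, periodHours(base) - d), 5e-3)
})

test_that("the rhythmicity score degrades monotonically with noise", {
  noise_levels <- c(5, 20, 50, 100, 200, 400)
  mean_r2 <- vapply(seq_along(noise_levels), function(k) {
    r2 <- vapply(1:12, function(i) {
      p <- simulationParams(noise_sd = noise_levels[k],
                           seed = 100L * k + i)
      tr <- smoothMovingAverage(detrendMovingAverage(simulateTrace(p)))
      rhythmicityScore(fitSinusoid(tr))
    }, numeric(1))
    mean(r2)
  }, numeric(1))
  expect_lt(cor(noise_levels, mean_r2, method = "spearman"), -0.9)

  # an SNR-1 trace scores between SNR-5 and pure noise from the same seeds
  score_at <- function(amp) {
    p <- simulationParams(amplitude0 = amp, noise_sd = 100, seed = 11L)
    tr <- smoothMovingAverage(detrendMovingAverage(simulateTrace(p)))
    rhythmicityScore(fitSinusoid(tr))
  }
  s5 <- score_at(500); s1 <- score_at(100); s0 <- score_at(0)
  expect_gt(s5, s1)
  expect_gt(s1, s0)
})

test_that("short traces and bad configs are refused", {
  short <- luminescenceTrace("A1", seq(0, 30, by = 0.2),
                             sin(seq(0, 30, by = 0.2)))
  expect_error(fitSinusoid(short), "at least")
  expect_error(fitConfig(period_bounds_h = c(40, 16)), "increasing")
  expect_error(fitConfig(coarse_step_h = 10), "coarse_step_h")
})
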