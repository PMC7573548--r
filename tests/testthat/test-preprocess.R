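t_grid <- seq(0, 72, by = 0.2)

test_that("detrending annihilates affine baselines on the retained region", {
  tr <- luminescenceTrace("A1", t_grid, 2 + 0.5 * t_grid)
  out <- detrendMovingAverage(tr)
  expect_lt(max(abs(traceSignal(out))), 1e-9)
  # trim drops half a 24-h window (60 samples) at each end
  expect_length(traceSignal(out), 361L - 120L)
  expect_identical(stepsApplied(out), "detrend_movavg")
})

test_that("a 24-h window passes a 24-h sinusoid untouched", {
  tr <- make_sine_trace(period = 24, amp = 1)
  out <- detrendMovingAverage(tr)
  expect_lt(max(abs(traceSignal(out) -
                    sin(2 * pi * traceTime(out) / 24))), 1e-6)
})

test_that("detrending matches a direct-convolution oracle on decay + rhythm", {
  y <- 100 * exp(-t_grid / 48) + 10 * sin(2 * pi * t_grid / 24)
  tr <- luminescenceTrace("A1", t_grid, y)
  out <- detrendMovingAverage(tr)
  ref <- y - oracle_running_mean(y, s = 120L)   # 24 h at 0.2 h
  expect_lt(max(abs(traceSignal(out) - ref[!is.na(ref)])), 1e-9)
  # and the de-trended rhythm still fits at its true period
  fit <- fitSinusoid(smoothMovingAverage(out))
  expect_lt(abs(periodHours(fit) - 24), 0.2)
})

test_that("smoothing preserves constants and obeys the 1/w variance law", {
  tr <- luminescenceTrace("A1", t_grid, rep(7, length(t_grid)))
  expect_equal(traceSignal(smoothMovingAverage(tr)),
               rep(7, 361L - 10L), tolerance = 1e-12)

  n <- 10000L
  tt <- seq(0, by = 0.2, length.out = n)
  y <- withr::with_seed(42L, rnorm(n))
  sm <- smoothMovingAverage(luminescenceTrace("A1", tt, y))
  # 2-h window = 11 samples; trapezoid kernel variance factor ~ 1/w
  expect_lt(abs(var(traceSignal(sm)) / (var(y) / 11) - 1), 0.15)
})

test_that("boxcar attenuation of a sinusoid follows the sinc closed form", {
  for (T in c(20, 24, 28)) {
    tr <- make_sine_trace(period = T, amp = 1)
    sm <- smoothMovingAverage(tr)
    # amplitude on the retained region via fixed-period OLS (no calibration)
    amp <- fitFixedPeriod(sm, T)$amplitude
    w <- 2
    expected <- abs(sin(pi * w / T) / (pi * w / T))
    expect_lt(abs(amp / expected - 1), 0.01)
  }
})

test_that("both filters are linear and commute with time shifts", {
  set.seed(7)
  x <- rnorm(361); y <- rnorm(361)
  mk <- function(v) luminescenceTrace("A1", t_grid, v)
  for (f in list(detrendMovingAverage, smoothMovingAverage)) {
    lhs <- traceSignal(f(mk(3 * x - 2 * y)))
    rhs <- 3 * traceSignal(f(mk(x))) - 2 * traceSignal(f(mk(y)))
    expect_lt(max(abs(lhs - rhs)), 1e-9)

    # dropping k leading samples shifts the retained output by k samples
    k <- 13L
    full <- traceSignal(f(mk(x)))
    shifted <- traceSignal(f(luminescenceTrace("A1", t_grid[1:(361 - k)],
                                               x[(k + 1):361])))
    m <- length(shifted)
    expect_lt(max(abs(shifted - full[(k + 1):(k + m)])), 1e-9)
  }
})

test_that("detrend + smooth preserve a sinusoid's zero-crossing spacing", {
  tr <- make_sine_trace(period = 25, amp = 10, phase = 3)
  out <- smoothMovingAverage(detrendMovingAverage(tr))
  y <- traceSignal(out); tt <- traceTime(out)
  idx <- which(y[-length(y)] < 0 & y[-1] >= 0)   # ascending crossings
  crossings <- tt[idx] - y[idx] * 0.2 / (y[idx + 1] - y[idx])
  expect_true(all(abs(diff(crossings) - 25) <= 0.2))
})

test_that("edge policies behave as declared", {
  tr <- luminescenceTrace("A1", t_grid, 2 + 0.5 * t_grid)
  shrunk <- detrendMovingAverage(tr, preprocessConfig(edge_policy = "shrink"))
  expect_length(traceSignal(shrunk), length(t_grid))
  # interior values agree with trim
  trimmed <- detrendMovingAverage(tr)
  expect_lt(max(abs(traceSignal(shrunk)[61:301] - traceSignal(trimmed))),
            1e-9)

  short <- luminescenceTrace("A1", seq(0, 40, by = 0.2),
                             seq(0, 40, by = 0.2))
  expect_error(detrendMovingAverage(short), "at least")
  wide <- luminescenceTrace("A1", seq(0, 72, by = 1), rnorm(73))
  expect_error(smoothMovingAverage(wide,
                                   preprocessConfig(smooth_window_h = 1)),
               "fewer than 3 samples")
})

test_that("replicate averaging reduces to the mean and tracks coherence", {
  # identical wells: the average is the common trace
  tr <- simulateTrace(simulationParams(seed = 5), "W01")
  plate <- plateRecording(
    list(tr, luminescenceTrace("W02", traceTime(tr), traceSignal(tr)),
         luminescenceTrace("W03", traceTime(tr), traceSignal(tr))),
    c(W01 = "X", W02 = "X", W03 = "X"))
  avg <- averageReplicates(plate, "X")
  expect_identical(wellId(avg), "X:mean")
  expect_equal(traceSignal(avg), traceSignal(tr), tolerance = 1e-12)
  expect_error(averageReplicates(plate, "Y"), "available: X")

  fit_amp <- function(trace) {
    amplitude(fitSinusoid(smoothMovingAverage(detrendMovingAverage(trace))))
  }
  # synchronized wells (common phase): averaging preserves amplitude
  sync <- simulatePlate(scenarioPreset("NIH3T3", n_wells = 3, seed = 1,
                                       phase_jitter_sd_h = 0))
  a_single <- fit_amp(getTrace(sync, "W01"))
  a_mean <- fit_amp(averageReplicates(sync, "NIH3T3"))
  expect_lt(abs(a_mean / a_single - 1), 0.10)

  # unsynchronized wells (phases uniform over the cycle): strong attenuation
  unsync <- simulatePlate(scenarioPreset("NIH3T3_unsync", n_wells = 24,
                                         seed = 3))
  a_un <- fit_amp(averageReplicates(unsync, "NIH3T3_unsync"))
  expect_lt(a_un / a_single, 0.30)
})
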