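#' @include AllClasses.R accessors.R
NULL

## Map OLS sine/cosine coefficients to the phase convention: the fitted
## curve is c + a*sin(wt) + b*cos(wt) = c + A*sin(w(t - phi)) with
## A = sqrt(a^2+b^2) and phi = (-atan2(b, a)/w) mod T, the time of the
## first ascending zero-crossing after t = 0.
.phaseFromCoef <- function(a, b, period_h) {
  phi <- (-atan2(b, a)) * period_h / (2 * pi)
  phi <- phi %% period_h
  if (phi >= period_h) phi <- phi - period_h   # guard %% rounding at T
  phi
}

#' Fit the constant-plus-sinusoid model at a fixed period
#'
#' At a known period the rhythmicity model
#' \eqn{y(t) = c + a\sin(2\pi t/T) + b\cos(2\pi t/T)} is linear in
#' \eqn{(c, a, b)} and is solved by ordinary least squares. The amplitude is
#' \eqn{\sqrt{a^2+b^2}} and the phase is the time of the fitted sinusoid's
#' first ascending zero-crossing after t = 0, mapped into `[0, period_h)`.
#'
#' @param trace A [LuminescenceTrace-class] with at least 4 samples.
#' @param period_h Candidate period, hours (> 0).
#' @return A list with elements `constant_level`, `amplitude`, `phase_h`,
#'   `sse`, and the raw coefficients `a`, `b`.
#' @examples
#' t <- seq(0, 72, by = 0.2)
#' tr <- luminescenceTrace("A1", t, 7 + 3 * sin(2 * pi * t / 24))
#' fitFixedPeriod(tr, 24)$amplitude
#' @export
fitFixedPeriod <- function(trace, period_h) {
  validObject(trace)
  if (length(trace@time_h) < 4L)
    stop("need at least 4 samples to fit 3 coefficients", call. = FALSE)
  if (!(period_h > 0)) stop("period_h must be > 0", call. = FALSE)
  w <- 2 * pi / period_h
  X <- cbind(intercept = 1, s = sin(w * trace@time_h),
             c = cos(w * trace@time_h))
  qr_ <- qr(X)
  if (qr_$rank < 3L)
    stop(sprintf(
      "design is rank-deficient at period %.4g h (aliasing with dt = %.3g h)",
      period_h, samplingInterval(trace)), call. = FALSE)
  cf <- unname(qr.coef(qr_, trace@signal))
  resid <- trace@signal - X %*% cf
  list(constant_level = cf[1L],
       amplitude = sqrt(cf[2L]^2 + cf[3L]^2),
       phase_h = .phaseFromCoef(cf[2L], cf[3L], period_h),
       sse = sum(resid^2),
       a = cf[2L], b = cf[3L])
}

## Exact gain of the centered trapezoidal running-mean kernel spanning
## window_h at sampling interval dt_h, for a sinusoid of period period_h:
## G(T) = sum_j w_j cos(2*pi*j*dt/T) over centered sample offsets j.
.kernelGain <- function(window_h, dt_h, period_h) {
  w <- .movingAverageWeights(window_h, dt_h)
  h <- (length(w) - 1L) %/% 2L
  sum(w * cos(2 * pi * ((-h):h) * dt_h / period_h))
}

## Net amplitude gain of the recorded preprocessing at period T: smoothing
## multiplies the oscillation by G_s(T); de-trending (subtraction of the
## running mean) by 1 - G_d(T). Both kernels are symmetric, hence zero-phase.
.provenanceGain <- function(trace, period_h) {
  dt <- samplingInterval(trace)
  g <- 1
  if (is.finite(trace@detrend_window_h))
    g <- g * (1 - .kernelGain(trace@detrend_window_h, dt, period_h))
  if (is.finite(trace@smooth_window_h))
    g <- g * .kernelGain(trace@smooth_window_h, dt, period_h)
  g
}

## Golden-section minimisation of f on [lo, hi] to tolerance tol.
.goldenSection <- function(f, lo, hi, tol) {
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo)
  x2 <- lo + gr * (hi - lo)
  f1 <- f(x1); f2 <- f(x2)
  while ((hi - lo) > tol) {
    if (f1 <= f2) {            # <=: ties move toward the smaller period
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- f(x1)
    } else {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- f(x2)
    }
  }
  (lo + hi) / 2
}

#' Fit period, amplitude, phase and rhythmicity score to a trace
#'
#' The computational core: a period-profiled least-squares fit of the model
#' "constant level plus one sinusoid". At each candidate period the
#' subproblem is exactly linear ([fitFixedPeriod()]); the profiled residual
#' sum of squares is scanned over `period_bounds_h` at `coarse_step_h`, and
#' the SSE-minimising candidate is refined by golden-section search to
#' `refine_tol_h`. The coefficient of determination
#' \eqn{R^2 = 1 - SSE/SST} (SST about the signal mean) is the rhythmicity
#' readout: how closely the conditioned trace follows a sinusoid.
#'
#' When the trace records filter provenance (windows applied by
#' [detrendMovingAverage()] / [smoothMovingAverage()]), the fitted
#' amplitude is divided by the exact gain of those zero-phase kernels at
#' the fitted period, so it refers to the unfiltered oscillation;
#' `r_squared` and `sse` remain defined on the conditioned signal as
#' fitted. Period and phase are unaffected (the kernels are symmetric).
#'
#' A trace whose total variance is below 1e-12 yields a degenerate fit
#' (`isDegenerate`, `R^2 = 0`, amplitude 0) rather than an error.
#' `isConverged` is `TRUE` only when the refined minimum is interior to the
#' search bounds. If two coarse-grid candidates tie to within 1e-12, the
#' smaller period seeds the refinement.
#'
#' @param x A [LuminescenceTrace-class], typically detrended and smoothed;
#'   its span must cover at least two periods at the lower search bound.
#' @param config A [FitConfig-class].
#' @return A [SinusoidFit-class].
#' @examples
#' t <- seq(0, 72, by = 0.2)
#' fit <- fitSinusoid(luminescenceTrace("A1", t, 5 * sin(2 * pi * t / 24)))
#' periodHours(fit)
#' @export
setMethod("fitSinusoid", "LuminescenceTrace",
          function(x, config = fitConfig()) {
  validObject(x); validObject(config)
  b <- config@period_bounds_h
  span <- diff(range(x@time_h))
  if (span < 2 * b[1L])
    stop(sprintf(
      "trace spans %.1f h; fitting needs at least %.1f h (2 periods at the lower bound)",
      span, 2 * b[1L]), call. = FALSE)
  y <- x@signal
  sst <- sum((y - mean(y))^2)
  if (sst < 1e-12)
    return(new("SinusoidFit", period_h = NA_real_, amplitude = 0,
               phase_h = NA_real_, constant_level = mean(y), r_squared = 0,
               sse = 0, converged = FALSE, degenerate = TRUE))

  periods <- seq(b[1L], b[2L], by = config@coarse_step_h)
  sse <- vapply(periods, function(p) fitFixedPeriod(x, p)$sse, numeric(1))
  k <- which(sse <= min(sse) + 1e-12)[1L]   # ties -> smaller period
  interior <- k > 1L && k < length(periods)
  lo <- periods[max(1L, k - 1L)]
  hi <- periods[min(length(periods), k + 1L)]
  p_hat <- .goldenSection(function(p) fitFixedPeriod(x, p)$sse,
                          lo, hi, config@refine_tol_h)
  fin <- fitFixedPeriod(x, p_hat)
  converged <- interior &&
    p_hat > b[1L] + config@refine_tol_h && p_hat < b[2L] - config@refine_tol_h
  # refer amplitude back to the unfiltered signal using the recorded
  # filter provenance (gain of the applied kernels at the fitted period)
  gain <- .provenanceGain(x, p_hat)
  if (is.finite(gain) && abs(gain) > 0.05)
    fin$amplitude <- fin$amplitude / abs(gain)
  new("SinusoidFit", period_h = p_hat, amplitude = fin$amplitude,
      phase_h = fin$phase_h, constant_level = fin$constant_level,
      r_squared = 1 - fin$sse / sst, sse = fin$sse,
      converged = converged, degenerate = FALSE)
})

#' Rhythmicity score of a fit
#'
#' Returns the fit's coefficient of determination clipped to `[0, 1]` for
#' reporting; the raw (possibly negative) value stays in the fit object. A
#' degenerate fit scores 0.
#'
#' @param fit A [SinusoidFit-class].
#' @return Numeric scalar in `[0, 1]`.
#' @export
rhythmicityScore <- function(fit) {
  stopifnot(is(fit, "SinusoidFit"))
  if (fit@degenerate) return(0)
  min(1, max(0, fit@r_squared))
}
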