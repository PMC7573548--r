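#' @include AllClasses.R accessors.R
NULL

## Centered moving-average kernel spanning exactly window_h hours at
## sampling interval dt_h: s = window_h/dt_h intervals (rounded to the
## nearest even count so the window is centred on a sample), s+1 samples
## with half-weights at the two ends. This trapezoidal kernel integrates a
## sinusoid over exactly one period to zero (no endpoint double count) and
## reproduces an affine function at the window centre exactly.
.movingAverageWeights <- function(window_h, dt_h) {
  s <- 2L * as.integer(round(window_h / (2 * dt_h)))
  if (s < 2L)
    stop(sprintf(
      "window of %.3g h spans fewer than 3 samples at dt = %.3g h",
      window_h, dt_h), call. = FALSE)
  c(0.5, rep(1, s - 1L), 0.5) / s
}

## Running weighted mean. edge_policy "trim" leaves NA in the half-window at
## each end; "shrink" fills them with progressively smaller centred
## trapezoidal windows (degenerating to the raw sample at the very ends).
.runningMean <- function(x, w, edge_policy) {
  n <- length(x)
  h <- (length(w) - 1L) %/% 2L
  if (n < length(w))
    stop(sprintf("trace has %d samples but the window needs %d",
                 n, length(w)), call. = FALSE)
  out <- as.numeric(stats::filter(x, w, sides = 2))
  if (edge_policy == "shrink" && h >= 1L) {
    for (i in c(seq_len(h), seq(n - h + 1L, n))) {
      hi <- min(i - 1L, n - i)
      out[i] <- if (hi == 0L) x[i] else {
        wi <- c(0.5, rep(1, 2L * hi - 1L), 0.5) / (2L * hi)
        sum(wi * x[(i - hi):(i + hi)])
      }
    }
  }
  out
}

## Shared driver: compute the running mean and either subtract it (detrend)
## or return it (smooth); drop the NA edges under "trim".
.applyFilter <- function(trace, window_h, edge_policy, subtract, label) {
  if (!isRegular(trace))
    stop("filtering requires regular sampling", call. = FALSE)
  dt <- samplingInterval(trace)
  w <- .movingAverageWeights(window_h, dt)
  m <- .runningMean(trace@signal, w, edge_policy)
  y <- if (subtract) trace@signal - m else m
  keep <- !is.na(y)
  out <- luminescenceTrace(trace@well_id, trace@time_h[keep], y[keep],
                           c(trace@steps_applied, label),
                           detrend_window_h = trace@detrend_window_h,
                           smooth_window_h = trace@smooth_window_h)
  # record filter provenance so the fit can refer amplitude back to the
  # unfiltered signal
  if (subtract) out@detrend_window_h <- window_h
  else out@smooth_window_h <- window_h
  out
}

#' De-trend a trace by subtracting its centered running mean
#'
#' Removes slow baseline components (cell proliferation, reporter/substrate
#' decline) by subtracting a centered running mean spanning
#' `detrend_window_h` hours, leaving the circadian band intact. Under the
#' default `edge_policy = "trim"` the first and last half-window of samples
#' are dropped; `"shrink"` retains them using smaller centered windows.
#'
#' The trace must be regularly sampled and at least twice the window long.
#'
#' @param x A [LuminescenceTrace-class] or [PlateRecording-class].
#' @param config A [PreprocessConfig-class].
#' @return Object of the same class with `"detrend_movavg"` appended to its
#'   applied steps.
#' @examples
#' tr <- simulateTrace(simulationParams(seed = 1))
#' dt <- detrendMovingAverage(tr)
#' stepsApplied(dt)
#' @export
setMethod("detrendMovingAverage", "LuminescenceTrace",
          function(x, config = preprocessConfig()) {
  validObject(config)
  span <- diff(range(x@time_h))
  if (span < 2 * config@detrend_window_h)
    stop(sprintf(
      "trace spans %.1f h but de-trending needs at least %.1f h (2 windows)",
      span, 2 * config@detrend_window_h), call. = FALSE)
  .applyFilter(x, config@detrend_window_h, config@edge_policy,
               subtract = TRUE, label = "detrend_movavg")
})

#' @rdname detrendMovingAverage-LuminescenceTrace-method
#' @export
setMethod("detrendMovingAverage", "PlateRecording",
          function(x, config = preprocessConfig()) {
  .mapPlate(x, function(tr) detrendMovingAverage(tr, config))
})

#' Smooth a trace with a centered moving average
#'
#' Suppresses fast technical noise with a centered running mean spanning
#' `smooth_window_h` hours. A boxcar this short attenuates a 24-h rhythm by
#' under 2 percent (the attenuation factor is ~sinc(w/T)) while cutting
#' white-noise variance roughly by the number of samples in the window.
#'
#' @inheritParams detrendMovingAverage,LuminescenceTrace-method
#' @return Object of the same class with `"smooth_movavg"` appended.
#' @export
setMethod("smoothMovingAverage", "LuminescenceTrace",
          function(x, config = preprocessConfig()) {
  validObject(config)
  .applyFilter(x, config@smooth_window_h, config@edge_policy,
               subtract = FALSE, label = "smooth_movavg")
})

#' @rdname smoothMovingAverage-LuminescenceTrace-method
#' @export
setMethod("smoothMovingAverage", "PlateRecording",
          function(x, config = preprocessConfig()) {
  .mapPlate(x, function(tr) smoothMovingAverage(tr, config))
})

## Apply a trace -> trace transform to every well of a plate, rebuilding the
## (possibly shorter) shared time axis.
.mapPlate <- function(plate, f) {
  trs <- lapply(traces(plate), f)
  plateRecording(trs, conditions(plate), replicates(plate))
}

#' Average the technical replicates of one condition
#'
#' Pointwise mean across all wells carrying `condition`, mirroring the
#' common display of bioluminescence curves as the average of technical
#' repeats. The result's well id is `"<condition>:mean"`.
#'
#' @param plate A [PlateRecording-class].
#' @param condition Condition label present in the plate metadata.
#' @return A [LuminescenceTrace-class].
#' @export
averageReplicates <- function(plate, condition) {
  cond <- conditions(plate)
  wells <- names(cond)[cond == condition]
  if (!length(wells))
    stop("unknown condition '", condition, "'; available: ",
         paste(unique(cond), collapse = ", "), call. = FALSE)
  mat <- SummarizedExperiment::assay(plate, "luminescence")[, wells,
                                                            drop = FALSE]
  md <- S4Vectors::metadata(plate)
  luminescenceTrace(paste0(condition, ":mean"), traceTime(plate),
                    rowMeans(mat), stepsApplied(plate),
                    detrend_window_h = if (is.null(md$detrend_window_h))
                      NA_real_ else md$detrend_window_h,
                    smooth_window_h = if (is.null(md$smooth_window_h))
                      NA_real_ else md$smooth_window_h)
}
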