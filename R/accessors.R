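#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn LuminescenceTrace-class Well identifier.
#' @param x A `LuminescenceTrace`.
#' @export
setMethod("wellId", "LuminescenceTrace", function(x) x@well_id)

#' @describeIn LuminescenceTrace-class Time axis, hours.
#' @export
setMethod("traceTime", "LuminescenceTrace", function(x) x@time_h)

#' @describeIn LuminescenceTrace-class Signal, luminescence counts.
#' @export
setMethod("traceSignal", "LuminescenceTrace", function(x) x@signal)

#' @describeIn LuminescenceTrace-class Labels of preprocessing steps applied.
#' @export
setMethod("stepsApplied", "LuminescenceTrace", function(x) x@steps_applied)

#' @describeIn LuminescenceTrace-class Median sampling interval, hours.
#' @export
setMethod("samplingInterval", "LuminescenceTrace",
          function(x) median(diff(x@time_h)))

#' @describeIn LuminescenceTrace-class `TRUE` when successive time
#'   differences agree to within 1e-6 h.
#' @export
setMethod("isRegular", "LuminescenceTrace", function(x) {
  d <- diff(x@time_h)
  (max(d) - min(d)) < .REGULAR_TOL_H
})

setMethod("show", "LuminescenceTrace", function(object) {
  cat(sprintf(
    "LuminescenceTrace '%s': %d points, %.1f-%.1f h (dt ~ %.3g h%s)\n",
    object@well_id, length(object@time_h), min(object@time_h),
    max(object@time_h), samplingInterval(object),
    if (isRegular(object)) ", regular" else ", irregular"))
  if (length(object@steps_applied))
    cat("  steps applied:", paste(object@steps_applied, collapse = " -> "),
        "\n")
})

#' @describeIn PlateRecording-class Well-to-condition map (named character).
#' @param x A `PlateRecording`.
#' @export
setMethod("conditions", "PlateRecording", function(x) {
  stats::setNames(SummarizedExperiment::colData(x)$condition, colnames(x))
})

#' @describeIn PlateRecording-class Well-to-replicate map (named integer).
#' @export
setMethod("replicates", "PlateRecording", function(x) {
  stats::setNames(SummarizedExperiment::colData(x)$replicate, colnames(x))
})

#' @describeIn PlateRecording-class Well identifiers.
#' @export
setMethod("wellIds", "PlateRecording", function(x) colnames(x))

#' @describeIn PlateRecording-class Shared time axis, hours.
#' @export
setMethod("traceTime", "PlateRecording",
          function(x) SummarizedExperiment::rowData(x)$time_h)

#' @describeIn PlateRecording-class Plate-wide preprocessing labels.
#' @export
setMethod("stepsApplied", "PlateRecording", function(x) {
  s <- S4Vectors::metadata(x)$steps_applied
  if (is.null(s)) character(0) else s
})

#' @describeIn PlateRecording-class Extract one well as a
#'   [LuminescenceTrace-class].
#' @param well Well identifier.
#' @export
setMethod("getTrace", "PlateRecording", function(x, well) {
  if (!well %in% colnames(x))
    stop("unknown well '", well, "'", call. = FALSE)
  md <- S4Vectors::metadata(x)
  luminescenceTrace(well, traceTime(x),
                    SummarizedExperiment::assay(x, "luminescence")[, well],
                    stepsApplied(x),
                    detrend_window_h = if (is.null(md$detrend_window_h))
                      NA_real_ else md$detrend_window_h,
                    smooth_window_h = if (is.null(md$smooth_window_h))
                      NA_real_ else md$smooth_window_h)
})

#' Extract all wells of a plate as a named list of traces
#'
#' @param x A [PlateRecording-class].
#' @return Named list of [LuminescenceTrace-class] objects, one per well.
#' @export
traces <- function(x) {
  stats::setNames(lapply(colnames(x), function(w) getTrace(x, w)),
                  colnames(x))
}

setMethod("show", "PlateRecording", function(object) {
  th <- traceTime(object)
  cat(sprintf("PlateRecording: %d wells x %d timepoints (%.1f-%.1f h)\n",
              ncol(object), nrow(object), min(th), max(th)))
  cond <- table(conditions(object))
  cat("  conditions:",
      paste(sprintf("%s (n=%d)", names(cond), as.integer(cond)),
            collapse = ", "), "\n")
  if (length(stepsApplied(object)))
    cat("  steps applied:", paste(stepsApplied(object), collapse = " -> "),
        "\n")
})

#' @describeIn SinusoidFit-class Fitted period, hours.
#' @param x A `SinusoidFit`.
#' @export
setMethod("periodHours", "SinusoidFit", function(x) x@period_h)

#' @describeIn SinusoidFit-class Fitted amplitude, counts.
#' @export
setMethod("amplitude", "SinusoidFit", function(x) x@amplitude)

#' @describeIn SinusoidFit-class Phase: first ascending zero-crossing after
#'   t = 0, hours in `[0, period)`.
#' @export
setMethod("phaseHours", "SinusoidFit", function(x) x@phase_h)

#' @describeIn SinusoidFit-class Fitted constant level, counts.
#' @export
setMethod("constantLevel", "SinusoidFit", function(x) x@constant_level)

#' @describeIn SinusoidFit-class Raw coefficient of determination.
#' @export
setMethod("rSquared", "SinusoidFit", function(x) x@r_squared)

#' @describeIn SinusoidFit-class Did refinement bracket an interior minimum.
#' @export
setMethod("isConverged", "SinusoidFit", function(x) x@converged)

#' @describeIn SinusoidFit-class Was the input (near-)constant.
#' @export
setMethod("isDegenerate", "SinusoidFit", function(x) x@degenerate)

setMethod("show", "SinusoidFit", function(object) {
  if (object@degenerate) {
    cat("SinusoidFit: degenerate (zero total variance); R^2 = 0\n")
    return(invisible(NULL))
  }
  cat(sprintf(
    "SinusoidFit: period %.3f h, amplitude %.4g, phase %.2f h, level %.4g\n",
    object@period_h, object@amplitude, object@phase_h,
    object@constant_level))
  cat(sprintf("  R^2 = %.4f, SSE = %.4g, converged: %s\n",
              object@r_squared, object@sse, object@converged))
})

setMethod("show", "SimulationParams", function(object) {
  cat(sprintf(
    "SimulationParams: T=%.1f h, A0=%.3g, damping=%.3g/h, noise sd=%.3g\n",
    object@period_h, object@amplitude0, object@damping_per_h,
    object@noise_sd))
  cat(sprintf(
    "  baseline %.3g -> %.3g (decay %.3g/h); jitter %.2g h, diffusion %.2g h/sqrt(h)\n",
    object@baseline0 + object@baseline_floor, object@baseline_floor,
    object@baseline_decay_per_h, object@phase_jitter_sd_h,
    object@phase_diffusion_sd_h_per_sqrt_h))
  cat(sprintf("  %.0f h at dt=%.2g h, %s, seed %d\n", object@duration_h,
              object@dt_h,
              if (object@synchronized) "synchronized" else "unsynchronized",
              object@seed))
})

setMethod("show", "ScenarioPreset", function(object) {
  cat(sprintf("ScenarioPreset '%s': %d wells\n", object@name, object@n_wells))
  show(object@params)
})
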