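#' @import methods
#' @importFrom stats sd rnorm runif median coef wilcox.test
#' @importFrom utils read.csv write.csv packageVersion
NULL

## Sampling is declared regular when the spread of successive time
## differences is below this (hours).
.REGULAR_TOL_H <- 1e-6

#' Single-well bioluminescence trace
#'
#' One well's luminescence time series: a strictly increasing time axis in
#' hours and a signal in (arbitrary) luminescence counts, together with an
#' ordered record of the preprocessing steps already applied to it.
#'
#' @slot well_id Character scalar well identifier (e.g. \code{"A1"}).
#' @slot time_h Numeric vector of time points, hours, strictly increasing.
#' @slot signal Numeric vector of luminescence counts, same length.
#' @slot steps_applied Character vector of preprocessing-step labels, in
#'   application order; empty for raw data.
#' @slot detrend_window_h,smooth_window_h Filter provenance: the window
#'   lengths (hours) of the de-trending/smoothing already applied, or `NA`.
#'   [fitSinusoid()] uses them to refer the fitted amplitude back to the
#'   unfiltered signal.
#'
#' @seealso [luminescenceTrace()] for the user constructor.
#' @export
setClass("LuminescenceTrace",
  representation(
    well_id = "character",
    time_h = "numeric",
    signal = "numeric",
    steps_applied = "character",
    detrend_window_h = "numeric",
    smooth_window_h = "numeric"
  ),
  prototype(steps_applied = character(0), detrend_window_h = NA_real_,
            smooth_window_h = NA_real_)
)

setValidity("LuminescenceTrace", function(object) {
  msgs <- character(0)
  if (length(object@well_id) != 1L || is.na(object@well_id) ||
      !nzchar(object@well_id))
    msgs <- c(msgs, "well_id must be a single non-empty string")
  n <- length(object@time_h)
  if (n != length(object@signal))
    msgs <- c(msgs, sprintf("time_h (length %d) and signal (length %d) differ",
                            n, length(object@signal)))
  if (n < 2L)
    msgs <- c(msgs, "a trace needs at least 2 time points")
  if (anyNA(object@time_h) || anyNA(object@signal))
    msgs <- c(msgs, "missing values are not permitted in time_h or signal")
  if (n >= 2L && !anyNA(object@time_h) && any(diff(object@time_h) <= 0))
    msgs <- c(msgs, sprintf(
      "time_h must be strictly increasing (first violation at row %d)",
      which(diff(object@time_h) <= 0)[1L] + 1L))
  if (length(msgs)) msgs else TRUE
})

#' Construct a LuminescenceTrace
#'
#' @param well_id Well identifier.
#' @param time_h Time axis in hours, strictly increasing.
#' @param signal Luminescence counts, same length as `time_h`.
#' @param steps_applied Preprocessing labels already applied (default none).
#' @return A [LuminescenceTrace-class] object.
#' @examples
#' tr <- luminescenceTrace("A1", seq(0, 72, by = 0.2),
#'                         sin(2 * pi * seq(0, 72, by = 0.2) / 24))
#' isRegular(tr)
#' @export
luminescenceTrace <- function(well_id, time_h, signal,
                              steps_applied = character(0),
                              detrend_window_h = NA_real_,
                              smooth_window_h = NA_real_) {
  new("LuminescenceTrace", well_id = as.character(well_id),
      time_h = as.numeric(time_h), signal = as.numeric(signal),
      steps_applied = as.character(steps_applied),
      detrend_window_h = as.numeric(detrend_window_h),
      smooth_window_h = as.numeric(smooth_window_h))
}

#' Plate of luminescence traces with condition metadata
#'
#' A `PlateRecording` holds a set of single-well traces sharing one time
#' axis, plus the well-to-condition and well-to-replicate maps. It extends
#' `SummarizedExperiment`: the `"luminescence"` assay is a timepoints-by-wells
#' matrix, `rowData` carries `time_h`, and `colData` carries `condition` and
#' `replicate`. Preprocessing steps applied plate-wide are recorded in
#' `metadata(x)$steps_applied`.
#'
#' @seealso [plateRecording()], [readPlate()], [simulatePlate()]
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("PlateRecording", contains = "SummarizedExperiment")

setValidity("PlateRecording", function(object) {
  msgs <- character(0)
  if (!"luminescence" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'luminescence' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!"time_h" %in% colnames(rd)) {
    msgs <- c(msgs, "rowData must contain time_h")
  } else {
    th <- rd$time_h
    if (length(th) >= 2L && any(diff(th) <= 0))
      msgs <- c(msgs, "time_h must be strictly increasing")
    if (anyNA(th)) msgs <- c(msgs, "time_h contains missing values")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("condition", "replicate") %in% colnames(cd)))
    msgs <- c(msgs, "colData must contain condition and replicate")
  else if (anyNA(cd$condition))
    msgs <- c(msgs, sprintf("condition missing for well '%s'",
                            colnames(object)[which(is.na(cd$condition))[1L]]))
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msgs <- c(msgs, "well ids must be present and unique")
  if (ncol(object) > 0 && anyNA(SummarizedExperiment::assay(object, "luminescence")))
    msgs <- c(msgs, "missing values are not permitted in the luminescence assay")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PlateRecording from traces
#'
#' All traces must share an identical time axis (element-wise), and every
#' well must appear exactly once in `conditions`.
#'
#' @param traces List of [LuminescenceTrace-class] objects.
#' @param conditions Named character vector mapping well id to condition.
#' @param replicates Named integer vector mapping well id to replicate index;
#'   defaults to 1, 2, ... within each condition.
#' @return A [PlateRecording-class].
#' @export
plateRecording <- function(traces, conditions, replicates = NULL) {
  if (length(traces) == 0L) stop("no traces", call. = FALSE)
  for (tr in traces) validObject(tr)
  wells <- vapply(traces, wellId, character(1))
  if (anyDuplicated(wells))
    stop("duplicate well id '", wells[duplicated(wells)][1L], "'", call. = FALSE)
  t0 <- traces[[1L]]@time_h
  for (tr in traces)
    if (length(tr@time_h) != length(t0) || any(tr@time_h != t0))
      stop("trace '", wellId(tr), "' does not share the plate time axis",
           call. = FALSE)
  missing <- setdiff(wells, names(conditions))
  if (length(missing))
    stop("no condition declared for well '", missing[1L], "'", call. = FALSE)
  if (anyDuplicated(names(conditions))) {
    dup <- names(conditions)[duplicated(names(conditions))][1L]
    stop("well '", dup, "' appears more than once in the metadata",
         call. = FALSE)
  }
  cond <- unname(conditions[wells])
  if (is.null(replicates)) {
    rep_idx <- stats::ave(seq_along(wells), cond, FUN = seq_along)
  } else {
    rep_idx <- as.integer(unname(replicates[wells]))
    rep_idx[is.na(rep_idx)] <- 1L
  }
  mat <- vapply(traces, function(tr) tr@signal, numeric(length(t0)))
  dimnames(mat) <- list(NULL, wells)
  steps <- unique(unlist(lapply(traces, stepsApplied)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(luminescence = mat),
    rowData = S4Vectors::DataFrame(time_h = t0),
    colData = S4Vectors::DataFrame(condition = cond, replicate = rep_idx,
                                   row.names = wells),
    metadata = list(steps_applied = as.character(steps),
                    detrend_window_h = traces[[1L]]@detrend_window_h,
                    smooth_window_h = traces[[1L]]@smooth_window_h)
  )
  new("PlateRecording", se)
}

#' Result of the constant-plus-sinusoid fit
#'
#' Houses the fitted parameters of the rhythmicity model
#' \eqn{y(t) = c + A \sin(2\pi (t - \phi)/T)}: the period \eqn{T} in hours,
#' amplitude \eqn{A} (counts), phase \eqn{\phi} (hours in \eqn{[0, T)}, the
#' time of the fitted curve's first ascending zero-crossing after t = 0),
#' the constant level \eqn{c}, and the coefficient of determination
#' \eqn{R^2 = 1 - SSE/SST} used as the rhythmicity readout.
#'
#' @slot period_h,amplitude,phase_h,constant_level,r_squared,sse Numeric
#'   scalars; see description.
#' @slot converged Logical: did period refinement bracket an interior minimum.
#' @slot degenerate Logical: input had (near-)zero total variance.
#' @export
setClass("SinusoidFit",
  representation(
    period_h = "numeric", amplitude = "numeric", phase_h = "numeric",
    constant_level = "numeric", r_squared = "numeric", sse = "numeric",
    converged = "logical", degenerate = "logical"
  )
)

setValidity("SinusoidFit", function(object) {
  msgs <- character(0)
  if (!is.na(object@amplitude) && object@amplitude < 0)
    msgs <- c(msgs, "amplitude must be >= 0")
  if (!is.na(object@sse) && object@sse < -1e-9)
    msgs <- c(msgs, "sse must be >= 0")
  if (!is.na(object@phase_h) && !is.na(object@period_h) &&
      (object@phase_h < 0 || object@phase_h >= object@period_h + 1e-9))
    msgs <- c(msgs, "phase_h must lie in [0, period_h)")
  if (length(msgs)) msgs else TRUE
})

#' Preprocessing configuration
#'
#' Window lengths, in hours, for baseline de-trending and noise smoothing,
#' and the edge policy. Windows are realised as centered filters with an odd
#' sample count spanning the requested length at the trace's sampling
#' interval (see the package vignette for the exact kernel).
#'
#' @slot detrend_window_h De-trending window, hours (default 24).
#' @slot smooth_window_h Smoothing window, hours (default 2).
#' @slot edge_policy `"trim"` (drop half a window at each end, default) or
#'   `"shrink"` (progressively smaller centered windows near the edges).
#' @export
setClass("PreprocessConfig",
  representation(detrend_window_h = "numeric", smooth_window_h = "numeric",
                 edge_policy = "character"),
  prototype(detrend_window_h = 24.0, smooth_window_h = 2.0,
            edge_policy = "trim")
)

setValidity("PreprocessConfig", function(object) {
  msgs <- character(0)
  if (!(object@smooth_window_h > 0))
    msgs <- c(msgs, "smooth_window_h must be > 0")
  if (!(object@detrend_window_h > object@smooth_window_h))
    msgs <- c(msgs, "detrend_window_h must exceed smooth_window_h")
  if (!object@edge_policy %in% c("trim", "shrink"))
    msgs <- c(msgs, "edge_policy must be 'trim' or 'shrink'")
  if (length(msgs)) msgs else TRUE
})

#' @rdname PreprocessConfig-class
#' @param detrend_window_h,smooth_window_h,edge_policy See slots.
#' @export
preprocessConfig <- function(detrend_window_h = 24.0, smooth_window_h = 2.0,
                             edge_policy = c("trim", "shrink")) {
  new("PreprocessConfig", detrend_window_h = detrend_window_h,
      smooth_window_h = smooth_window_h,
      edge_policy = match.arg(edge_policy))
}

#' Period-search configuration for the sinusoid fit
#'
#' @slot period_bounds_h Search interval for the period, hours
#'   (default 16-40 h, bracketing circadian periods with margin).
#' @slot coarse_step_h Coarse grid step for the profiled-SSE scan (default
#'   0.05 h).
#' @slot refine_tol_h Golden-section refinement tolerance (default 1e-3 h).
#' @export
setClass("FitConfig",
  representation(period_bounds_h = "numeric", coarse_step_h = "numeric",
                 refine_tol_h = "numeric"),
  prototype(period_bounds_h = c(16.0, 40.0), coarse_step_h = 0.05,
            refine_tol_h = 1e-3)
)

setValidity("FitConfig", function(object) {
  msgs <- character(0)
  b <- object@period_bounds_h
  if (length(b) != 2L || !(b[1L] < b[2L]) || b[1L] <= 0)
    msgs <- c(msgs, "period_bounds_h must be an increasing positive pair")
  if (length(b) == 2L && !(object@coarse_step_h > 0 &&
                           object@coarse_step_h < (b[2L] - b[1L]) / 10))
    msgs <- c(msgs, "coarse_step_h must be positive and < (upper-lower)/10")
  if (!(object@refine_tol_h > 0))
    msgs <- c(msgs, "refine_tol_h must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' @rdname FitConfig-class
#' @param period_bounds_h,coarse_step_h,refine_tol_h See slots.
#' @export
fitConfig <- function(period_bounds_h = c(16.0, 40.0), coarse_step_h = 0.05,
                      refine_tol_h = 1e-3) {
  new("FitConfig", period_bounds_h = as.numeric(period_bounds_h),
      coarse_step_h = coarse_step_h, refine_tol_h = refine_tol_h)
}

#' Generative parameters for synthetic traces
#'
#' Defines the signal class the analysis assumes: a decaying baseline
#' \eqn{B_f + B_0 e^{-\beta t}}, an exponentially damped sinusoid
#' \eqn{A_0 e^{-\lambda t} \sin(2\pi (t - \phi_t)/T)} whose phase carries a
#' per-well synchronization jitter and an optional within-well random walk,
#' plus i.i.d. Gaussian noise. Identical seeds give bit-identical traces.
#'
#' @slot period_h True period T, hours.
#' @slot amplitude0 Initial oscillation amplitude, counts.
#' @slot damping_per_h Exponential amplitude decay rate \eqn{\lambda}, 1/h.
#' @slot baseline0,baseline_decay_per_h,baseline_floor Baseline start level,
#'   decay rate and asymptote, counts / 1/h / counts.
#' @slot noise_sd Additive Gaussian noise sd, counts.
#' @slot phase0_h Common phase offset at synchronization, hours.
#' @slot phase_jitter_sd_h Across-well phase jitter sd at t = 0, hours.
#' @slot phase_diffusion_sd_h_per_sqrt_h Within-well phase random-walk
#'   intensity, hours per sqrt(hour).
#' @slot duration_h,dt_h Recording length and sampling interval, hours.
#' @slot synchronized If `FALSE`, the well's phase is drawn uniformly on
#'   `[0, period_h)` instead of jittered around `phase0_h`.
#' @slot seed Integer RNG seed.
#' @export
setClass("SimulationParams",
  representation(
    period_h = "numeric", amplitude0 = "numeric", damping_per_h = "numeric",
    baseline0 = "numeric", baseline_decay_per_h = "numeric",
    baseline_floor = "numeric", noise_sd = "numeric", phase0_h = "numeric",
    phase_jitter_sd_h = "numeric", phase_diffusion_sd_h_per_sqrt_h = "numeric",
    duration_h = "numeric", dt_h = "numeric", synchronized = "logical",
    seed = "integer"
  ),
  prototype(
    period_h = 24.0, amplitude0 = 100, damping_per_h = 0.01,
    baseline0 = 500, baseline_decay_per_h = 0.02, baseline_floor = 50,
    noise_sd = 20, phase0_h = 0, phase_jitter_sd_h = 0.5,
    phase_diffusion_sd_h_per_sqrt_h = 0.02, duration_h = 72, dt_h = 0.2,
    synchronized = TRUE, seed = 1L
  )
)

setValidity("SimulationParams", function(object) {
  msgs <- character(0)
  chk_nonneg <- c("amplitude0", "damping_per_h", "baseline0",
                  "baseline_decay_per_h", "baseline_floor", "noise_sd",
                  "phase_jitter_sd_h", "phase_diffusion_sd_h_per_sqrt_h")
  for (f in chk_nonneg)
    if (slot(object, f) < 0)
      msgs <- c(msgs, sprintf("%s must be non-negative", f))
  if (!(object@period_h > 0)) msgs <- c(msgs, "period_h must be > 0")
  if (!(object@dt_h > 0)) msgs <- c(msgs, "dt_h must be > 0")
  if (object@period_h > 0 && object@dt_h > 0 &&
      !(object@dt_h < object@period_h / 8))
    msgs <- c(msgs, "dt_h must be < period_h/8 (Nyquist-safe sampling)")
  if (!(object@duration_h >= 48))
    msgs <- c(msgs, "duration_h must be >= 48")
  if (object@period_h > 0 && !(object@duration_h >= 2 * object@period_h))
    msgs <- c(msgs, "duration_h must be >= 2*period_h")
  if (length(msgs)) msgs else TRUE
})

#' @rdname SimulationParams-class
#' @param ... Slot values overriding the defaults (see slots).
#' @export
simulationParams <- function(...) {
  args <- list(...)
  if (!is.null(args$seed)) args$seed <- as.integer(args$seed)
  do.call(new, c(list("SimulationParams"), args))
}

#' A named simulation scenario
#'
#' Bundles [SimulationParams-class] with a condition name and well count;
#' see [scenarioPreset()] for the built-in cell-line and knockdown presets.
#'
#' @slot name Condition label.
#' @slot params The generative parameters.
#' @slot n_wells Number of wells to simulate.
#' @export
setClass("ScenarioPreset",
  representation(name = "character", params = "SimulationParams",
                 n_wells = "integer")
)

setValidity("ScenarioPreset", function(object) {
  if (length(object@n_wells) != 1L || object@n_wells < 1L)
    "n_wells must be a positive integer" else TRUE
})
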