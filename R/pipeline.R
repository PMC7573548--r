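#' @include AllClasses.R accessors.R preprocess.R rhythm-fit.R
NULL

.fitToRow <- function(fit) {
  data.frame(period_h = fit@period_h, amplitude = fit@amplitude,
             phase_h = fit@phase_h, constant_level = fit@constant_level,
             r_squared = fit@r_squared, rhythmicity = rhythmicityScore(fit),
             sse = fit@sse, converged = fit@converged,
             degenerate = fit@degenerate)
}

#' Run the full rhythmicity pipeline over a plate
#'
#' For every well: de-trend, smooth, fit the constant-plus-sinusoid model;
#' then aggregate fits per condition as mean and standard error of the mean.
#' Degenerate and non-converged wells are counted but excluded from the
#' parameter means, and each exclusion is recorded in the run log. With
#' `fit_mean = TRUE` the replicate-averaged trace of each condition is
#' fitted instead of (in addition to) the per-well fits, for parity with
#' figures that display averaged curves.
#'
#' @param plate A [PlateRecording-class].
#' @param preprocess_cfg A [PreprocessConfig-class].
#' @param fit_cfg A [FitConfig-class].
#' @param fit_mean Also fit each condition's replicate-averaged trace.
#' @return A list of class `"rhythmPipelineResult"` with components
#'   `fits` (one row per well: identifiers plus all [SinusoidFit-class]
#'   fields), `summaries` (one [summarizeCondition()] row per condition),
#'   `mean_fits` (per-condition fits of the averaged trace, or `NULL`),
#'   `log` (character vector of processing messages) and `config` (the
#'   effective configuration).
#' @examples
#' plate <- simulatePlate(scenarioPreset("NIH3T3", n_wells = 3, seed = 1))
#' res <- runPipeline(plate)
#' res$summaries
#' @export
runPipeline <- function(plate, preprocess_cfg = preprocessConfig(),
                        fit_cfg = fitConfig(), fit_mean = FALSE) {
  validObject(plate); validObject(preprocess_cfg); validObject(fit_cfg)
  cond <- conditions(plate)
  reps <- replicates(plate)
  log <- c(sprintf("pipeline: %d wells, %d timepoints", ncol(plate),
                   nrow(plate)),
           sprintf("detrend window %.3g h, smooth window %.3g h, edges: %s",
                   preprocess_cfg@detrend_window_h,
                   preprocess_cfg@smooth_window_h,
                   preprocess_cfg@edge_policy),
           sprintf("period search [%.3g, %.3g] h, step %.3g h, tol %.2g h",
                   fit_cfg@period_bounds_h[1L], fit_cfg@period_bounds_h[2L],
                   fit_cfg@coarse_step_h, fit_cfg@refine_tol_h))

  fitOne <- function(tr) {
    tr <- detrendMovingAverage(tr, preprocess_cfg)
    tr <- smoothMovingAverage(tr, preprocess_cfg)
    fitSinusoid(tr, fit_cfg)
  }

  rows <- lapply(wellIds(plate), function(w) {
    fit <- tryCatch(fitOne(getTrace(plate, w)), error = function(e)
      stop("well '", w, "': ", conditionMessage(e), call. = FALSE))
    cbind(data.frame(well_id = w, condition = unname(cond[w]),
                     replicate = unname(reps[w])), .fitToRow(fit))
  })
  fits <- do.call(rbind, rows)
  excl <- fits$well_id[fits$degenerate | !fits$converged]
  for (w in excl)
    log <- c(log, sprintf(
      "well '%s' excluded from condition means (%s)", w,
      if (fits$degenerate[fits$well_id == w]) "degenerate"
      else "non-converged"))

  summaries <- do.call(rbind, lapply(unique(fits$condition), function(cc)
    summarizeCondition(fits[fits$condition == cc, ], cc)))

  mean_fits <- NULL
  if (fit_mean) {
    mean_fits <- do.call(rbind, lapply(unique(cond), function(cc) {
      fit <- fitOne(averageReplicates(plate, cc))
      cbind(data.frame(condition = cc), .fitToRow(fit))
    }))
    log <- c(log, sprintf("fitted replicate-averaged trace for %d condition(s)",
                          length(unique(cond))))
  }

  structure(list(fits = fits, summaries = summaries, mean_fits = mean_fits,
                 log = log,
                 config = list(preprocess = preprocess_cfg, fit = fit_cfg,
                               fit_mean = fit_mean)),
            class = "rhythmPipelineResult")
}

#' @export
print.rhythmPipelineResult <- function(x, ...) {
  cat(sprintf("Rhythmicity pipeline result: %d wells, %d condition(s)\n",
              nrow(x$fits), nrow(x$summaries)))
  print(x$summaries, row.names = FALSE)
  invisible(x)
}

#' Aggregate sinusoid fits of one condition
#'
#' Means and standard errors of the mean (sd/sqrt(n)) of period, amplitude
#' and R-squared across a condition's wells. Degenerate and non-converged
#' fits are excluded from the means but counted in `n_wells`; SEMs are `NA`
#' when fewer than two fits contribute.
#'
#' @param fits Either a data frame of per-well fits (as in the `fits`
#'   component of [runPipeline()]'s result) or a list of
#'   [SinusoidFit-class] objects.
#' @param condition Condition label for the output row.
#' @return A one-row data frame: `condition`, `n_wells`, `n_converged`,
#'   `period_mean_h`, `period_sem_h`, `amplitude_mean`, `amplitude_sem`,
#'   `r2_mean`, `r2_sem`.
#' @export
summarizeCondition <- function(fits, condition) {
  if (is.list(fits) && !is.data.frame(fits) &&
      all(vapply(fits, is, logical(1), "SinusoidFit")))
    fits <- do.call(rbind, lapply(fits, .fitToRow))
  if (!is.data.frame(fits) || nrow(fits) == 0L)
    stop("no fits to summarize for condition '", condition, "'",
         call. = FALSE)
  ok <- !fits$degenerate & fits$converged
  sel <- fits[ok, , drop = FALSE]
  mstat <- function(v) {
    n <- sum(!is.na(v))
    c(mean = if (n) mean(v, na.rm = TRUE) else NA_real_,
      sem = if (n >= 2L) stats::sd(v, na.rm = TRUE) / sqrt(n) else NA_real_)
  }
  p <- mstat(sel$period_h); a <- mstat(sel$amplitude); r <- mstat(sel$r_squared)
  data.frame(condition = condition, n_wells = nrow(fits),
             n_converged = sum(ok),
             period_mean_h = unname(p["mean"]), period_sem_h = unname(p["sem"]),
             amplitude_mean = unname(a["mean"]), amplitude_sem = unname(a["sem"]),
             r2_mean = unname(r["mean"]), r2_sem = unname(r["sem"]))
}

#' Write a pipeline result as a reproducible report
#'
#' Writes `fits.csv` (per-well fits), `summaries.csv` (condition
#' aggregates), `mean_fits.csv` (if present) and `run_metadata.yml` (the
#' effective configuration, applied steps and package version) into `dir`.
#' The files are deterministic: identical inputs and configuration yield
#' byte-identical reports.
#'
#' @param result A [runPipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeFitReport <- function(result, dir) {
  stopifnot(inherits(result, "rhythmPipelineResult"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("fits.csv", "summaries.csv"))
  utils::write.csv(result$fits, paths[1L], row.names = FALSE, quote = FALSE)
  utils::write.csv(result$summaries, paths[2L], row.names = FALSE,
                   quote = FALSE)
  if (!is.null(result$mean_fits)) {
    p <- file.path(dir, "mean_fits.csv")
    utils::write.csv(result$mean_fits, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  pp <- result$config$preprocess; fc <- result$config$fit
  meta <- list(
    package = "LumiRhythm",
    version = as.character(utils::packageVersion("LumiRhythm")),
    preprocess = list(detrend_window_h = pp@detrend_window_h,
                      smooth_window_h = pp@smooth_window_h,
                      edge_policy = pp@edge_policy),
    fit = list(period_bounds_h = as.list(fc@period_bounds_h),
               coarse_step_h = fc@coarse_step_h,
               refine_tol_h = fc@refine_tol_h),
    fit_mean = result$config$fit_mean,
    log = as.list(result$log)
  )
  mp <- file.path(dir, "run_metadata.yml")
  yaml::write_yaml(meta, mp)
  invisible(c(paths, mp))
}

#' Ellipsoid tumor volume from caliper measurements
#'
#' The standard caliper formula \eqn{V = W^2 L / 2} (width squared times
#' length over two), in cubic millimetres. Note the asymmetry: width and
#' length are not interchangeable.
#'
#' @param width_mm,length_mm Non-negative caliper measurements, mm.
#' @return Volume in mm^3 (vectorised).
#' @examples
#' tumorVolume(5, 10)   # 125
#' @export
tumorVolume <- function(width_mm, length_mm) {
  if (any(width_mm < 0, na.rm = TRUE) || any(length_mm < 0, na.rm = TRUE))
    stop("width_mm and length_mm must be non-negative", call. = FALSE)
  width_mm^2 * length_mm / 2
}

#' Organ-to-body weight ratio
#'
#' Dimensionless organ burden readout, e.g. liver weight over body weight.
#'
#' @param organ_weight_g,body_weight_g Positive weights, grams.
#' @return `organ_weight_g / body_weight_g` (vectorised).
#' @examples
#' organBodyRatio(1.5, 25)   # 0.06
#' @export
organBodyRatio <- function(organ_weight_g, body_weight_g) {
  if (any(organ_weight_g <= 0, na.rm = TRUE) ||
      any(body_weight_g <= 0, na.rm = TRUE))
    stop("weights must be positive", call. = FALSE)
  organ_weight_g / body_weight_g
}
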