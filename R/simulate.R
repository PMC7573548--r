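#' @include AllClasses.R accessors.R
NULL

## Deterministic per-well seed from a plate seed: keeps seeds distinct
## across wells and below 2^31.
.wellSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i) %% .Machine$integer.max)
}

#' Simulate one bioluminescence trace
#'
#' Draws a synthetic well according to
#' \deqn{y(t_i) = B_f + B_0 e^{-\beta t_i} +
#'       A_0 e^{-\lambda t_i} \sin(2\pi (t_i - \phi_i)/T) + \epsilon_i,}
#' where the phase \eqn{\phi_i} is the common offset `phase0_h` plus one
#' per-well Gaussian jitter draw (sd `phase_jitter_sd_h`, the operational
#' meaning of dexamethasone synchronization) plus a cumulative Gaussian
#' random walk with per-step sd
#' `phase_diffusion_sd_h_per_sqrt_h * sqrt(dt_h)`, and
#' \eqn{\epsilon_i} is i.i.d. Gaussian noise with sd `noise_sd`. With
#' `synchronized = FALSE` the well's initial phase is instead drawn
#' uniformly on `[0, period_h)`. Identical seeds give bit-identical traces;
#' the caller's RNG state is left untouched.
#'
#' @param params A [SimulationParams-class].
#' @param well_id Well identifier for the returned trace.
#' @return A raw [LuminescenceTrace-class] (no preprocessing steps).
#' @examples
#' tr <- simulateTrace(simulationParams(period_h = 26.3, seed = 7))
#' @export
simulateTrace <- function(params, well_id = "W01") {
  validObject(params)
  t <- seq(0, params@duration_h, by = params@dt_h)
  n <- length(t)
  y <- withr::with_seed(params@seed, {
    phase0 <- if (params@synchronized)
      params@phase0_h + rnorm(1L, 0, params@phase_jitter_sd_h)
    else
      runif(1L, 0, params@period_h)
    walk <- c(0, cumsum(rnorm(
      n - 1L, 0, params@phase_diffusion_sd_h_per_sqrt_h * sqrt(params@dt_h))))
    eps <- if (params@noise_sd > 0) rnorm(n, 0, params@noise_sd) else
      numeric(n)
    baseline <- params@baseline_floor +
      params@baseline0 * exp(-params@baseline_decay_per_h * t)
    osc <- params@amplitude0 * exp(-params@damping_per_h * t) *
      sin(2 * pi * (t - phase0 - walk) / params@period_h)
    baseline + osc + eps
  })
  luminescenceTrace(well_id, t, y)
}

#' Built-in simulation scenarios
#'
#' Returns a named [ScenarioPreset-class]. Cell-line presets use the
#' reported circadian periods of the corresponding Per2::luc lines --
#' `MC38` 26.3 h, `E0771` 27.2 h, `LLC` 28.3 h -- with slightly stronger
#' damping than the fibroblast preset, reflecting their less robust
#' rhythms. `NIH3T3` uses a placeholder period of 24.0 h: the fibroblast
#' period is known to be shorter than all three cancer lines but its value
#' is not published, so a canonical circadian default is used. Knockdown
#' presets apply [knockdownScenario()] to the fibroblast parameters:
#' `siControl` (efficiency 0), `siPer1`, `siPer2` and `siPer1Per2`
#' (efficiency 0.8). `NIH3T3_unsync` draws well phases uniformly over the
#' cycle, emulating an unsynchronized culture.
#'
#' All presets share the sampling design of a LumiCycle run: 72 h at 0.2-h
#' (12-min) cadence, amplitude 100 counts over a decaying baseline, and
#' noise sd 20 counts (signal-to-noise 5).
#'
#' @param name Preset name (see Details).
#' @param n_wells Number of wells (default 12).
#' @param seed Plate seed; per-well seeds are derived deterministically
#'   from it (`(seed * 1009 + well) mod (2^31 - 1)`).
#' @param ... Overrides passed to [simulationParams()] on top of the
#'   preset's parameters.
#' @return A [ScenarioPreset-class].
#' @examples
#' scenarioPreset("MC38", n_wells = 3, seed = 7)
#' @export
scenarioPreset <- function(name, n_wells = 12L, seed = 1L, ...) {
  base <- list(seed = as.integer(seed))
  kd <- 0
  switch(name,
    NIH3T3 = { base$period_h <- 24.0 },
    NIH3T3_unsync = { base$period_h <- 24.0; base$synchronized <- FALSE },
    MC38 = { base$period_h <- 26.3; base$damping_per_h <- 0.015 },
    E0771 = { base$period_h <- 27.2; base$damping_per_h <- 0.015 },
    LLC = { base$period_h <- 28.3; base$damping_per_h <- 0.015 },
    siControl = { base$period_h <- 24.0 },
    siPer1 = { base$period_h <- 24.0; kd <- 0.8 },
    siPer2 = { base$period_h <- 24.0; kd <- 0.8 },
    siPer1Per2 = { base$period_h <- 24.0; kd <- 0.8 },
    stop("unknown preset '", name, "'; available: NIH3T3, NIH3T3_unsync, ",
         "MC38, E0771, LLC, siControl, siPer1, siPer2, siPer1Per2",
         call. = FALSE)
  )
  params <- do.call(simulationParams, utils::modifyList(base, list(...)))
  if (kd > 0) params <- knockdownScenario(params, kd)
  new("ScenarioPreset", name = name, params = params,
      n_wells = as.integer(n_wells))
}

#' Simulate a whole plate for a scenario
#'
#' Simulates `n_wells` independent wells whose seeds are derived
#' deterministically from the preset seed, and assembles them into a
#' [PlateRecording-class] with the preset name as condition and replicate
#' indices 1..n.
#'
#' @param preset A [ScenarioPreset-class], e.g. from [scenarioPreset()].
#' @return A [PlateRecording-class].
#' @examples
#' plate <- simulatePlate(scenarioPreset("NIH3T3", n_wells = 3, seed = 1))
#' @export
simulatePlate <- function(preset) {
  validObject(preset)
  wells <- sprintf("W%02d", seq_len(preset@n_wells))
  trs <- lapply(seq_len(preset@n_wells), function(i) {
    p <- preset@params
    p@seed <- .wellSeed(preset@params@seed, i)
    simulateTrace(p, wells[i])
  })
  plateRecording(trs,
                 stats::setNames(rep(preset@name, length(wells)), wells),
                 stats::setNames(seq_along(wells), wells))
}

#' Derive knockdown parameters from a baseline scenario
#'
#' Phenomenological model of clock-gene knockdown: rhythm impairment is
#' expressed as amplitude loss, faster damping and stronger phase
#' diffusion. At efficiency \eqn{e \in [0, 1]} the baseline parameters map
#' to `amplitude0 * (1 - 0.6 e)`, `damping_per_h * (1 + 2 e)` and
#' `phase_diffusion_sd_h_per_sqrt_h * (1 + 4 e)`; efficiency 0 is the
#' identity. The coefficients are tuning constants chosen so that a
#' full-efficiency knockdown visibly flattens replicate-averaged curves.
#'
#' @param base A [SimulationParams-class].
#' @param efficiency Knockdown efficiency in `[0, 1]`.
#' @return A modified [SimulationParams-class].
#' @export
knockdownScenario <- function(base, efficiency) {
  stopifnot(is(base, "SimulationParams"))
  if (!is.numeric(efficiency) || length(efficiency) != 1L ||
      is.na(efficiency) || efficiency < 0 || efficiency > 1)
    stop("efficiency must be a single value in [0, 1]", call. = FALSE)
  base@amplitude0 <- base@amplitude0 * (1 - 0.6 * efficiency)
  base@damping_per_h <- base@damping_per_h * (1 + 2 * efficiency)
  base@phase_diffusion_sd_h_per_sqrt_h <-
    base@phase_diffusion_sd_h_per_sqrt_h * (1 + 4 * efficiency)
  validObject(base)
  base
}
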