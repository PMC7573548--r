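---
title: "Rhythmicity analysis of bioluminescence reporter recordings"
author: "LumiRhythm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rhythmicity analysis of bioluminescence reporter recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LumiRhythm)
```

# The measurement and the model

Cultured cells carrying a Per2::luc reporter emit light in proportion to
*Per2* promoter activity. After a synchronizing dexamethasone pulse, a plate
luminometer (e.g. a LumiCycle) records each well every 12 minutes (0.2 h)
for three or more days. The raw trace is an oscillation of roughly one cycle
per day riding on a large, slowly decaying baseline (cell proliferation,
luciferin consumption, reporter decline), with additive technical noise.

LumiRhythm quantifies the rhythm of each well with a three-stage pipeline:

1. **De-trending** — subtract a centered 24-h running mean, removing the
   baseline while leaving the circadian band essentially untouched.
2. **Smoothing** — a centered 2-h running mean to suppress technical noise.
3. **Fitting** — least-squares regression of a *constant level plus one
   sinusoid*,
   $$ y(t) \;=\; c + A\,\sin\!\big(2\pi (t-\phi)/T\big) + \varepsilon(t), $$
   reporting the period $T$ (hours), amplitude $A$ (counts), phase $\phi$
   (hours), constant level $c$, and the coefficient of determination
   $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$ as the rhythmicity score: how
   closely the conditioned trace follows a sinusoid.

At a fixed candidate period the model is linear in $(c, a, b)$ via
$a\sin(\omega t) + b\cos(\omega t)$, so the fit is *period-profiled least
squares*: an exact OLS solve at each candidate period, a coarse scan of the
profiled SSE over the period search range, and golden-section refinement of
the minimum. This is globally robust, deterministic, and directly checkable
against a brute-force dense grid, which generic multi-start nonlinear
optimisation is not. If two coarse candidates tie within $10^{-12}$, the
smaller period is refined (determinism). A fit is `converged` only when the
refined minimum is interior to the search range; a trace with (near-)zero
variance yields a `degenerate` fit with $R^2 = 0$ rather than an error.

# Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `detrend_window_h` | 24 h | span of the baseline-removal running mean |
| `smooth_window_h` | 2 h | span of the denoising running mean |
| `edge_policy` | `"trim"` | drop half a window at each end, or `"shrink"` |
| `period_bounds_h` | 16–40 h | period search range |
| `coarse_step_h` | 0.05 h | SSE scan step |
| `refine_tol_h` | 0.001 h | golden-section tolerance |

The 24-h de-trending window is the standard choice for circadian records: a
running mean spanning exactly one nominal cycle annihilates the rhythm's
contribution to the trend estimate. The 2-h smoothing window (11 samples at
0.2 h) attenuates a 24-h rhythm by only $\operatorname{sinc}(2/24) \approx
1.1\%$ while cutting white-noise variance roughly 11-fold. The search bounds
16–40 h bracket all plausible mammalian circadian periods with margin.

## The moving-average kernel

Both filters use a centered window spanning exactly the requested length
$w$: with $s = w/\Delta t$ sampling intervals ($s$ rounded to an even
count), the kernel has $s+1$ points with half-weights at the two ends
(the classical "$2\times m$" centered moving average). This choice is
deliberate:

* the window covers a full period of a $w$-periodic sinusoid *without
  double-counting an endpoint*, so a 24-h window annihilates a 24-h rhythm
  exactly;
* symmetric weights reproduce any affine baseline exactly at the window
  center, so de-trending removes linear drift to machine precision;
* the frequency response matches the continuous boxcar's
  $\operatorname{sinc}(w/T)$ closely (within 0.1% at circadian periods).

Under `edge_policy = "trim"` the half-window at each end is dropped — the
default, because shrinking windows near the edges let the trend estimate
track the oscillation itself, which biases the subsequent fit appreciably.
`"shrink"` is available for records too short to afford trimming.

## Phase and amplitude conventions

Phase is reported as the time, in $[0, T)$, of the fitted sinusoid's first
ascending zero-crossing after $t = 0$ — an unambiguous convention (e.g. a
pure cosine of period 24 h has phase 18 h). Because both filters are
zero-phase, preprocessing never shifts it.

Filters do scale the oscillation: de-trending multiplies the circadian
component by $1 - G_d(T)$ and smoothing by $G_s(T)$, where $G$ is the exact
discrete kernel gain. Traces record the windows applied to them, and
`fitSinusoid` divides the fitted amplitude by the net recorded gain at the
fitted period, so reported amplitudes refer to the *unfiltered* oscillation
and are comparable across conditions with different periods. $R^2$ and SSE
remain defined on the conditioned signal actually fitted.

# The synthetic-data generator

Real LumiCycle exports for this assay class are not publicly deposited, so
the package ships a generator that emulates the recording design:
dexamethasone-synchronized wells sampled every 0.2 h for 72 h,

$$ y(t_i) = B_f + B_0 e^{-\beta t_i}
   + A_0 e^{-\lambda t_i} \sin\!\big(2\pi (t_i - \phi_i)/T\big)
   + \varepsilon_i , $$

with a per-well phase jitter at $t=0$ (sd 0.5 h — the operational meaning of
synchronization), an optional within-well Gaussian phase random walk, and
i.i.d. Gaussian noise. Defaults: amplitude 100 counts, noise sd 20
(signal-to-noise 5), baseline 500 decaying at 0.02/h over a floor of 50,
damping 0.01/h (0.015/h for the cancer-line presets, whose rhythms are less
robust than fibroblasts'), phase diffusion 0.02 h/√h. Presets `MC38`,
`E0771` and `LLC` use the reported periods of those Per2::luc lines (26.3,
27.2, 28.3 h). The fibroblast preset `NIH3T3` uses 24.0 h — a placeholder:
the fibroblast period is known only to be shorter than the three cancer
lines, so the canonical circadian value is used. Knockdown presets map an
efficiency $e$ phenomenologically to amplitude $\times(1-0.6e)$, damping
$\times(1+2e)$ and phase diffusion $\times(1+4e)$; `siPer1`, `siPer2` and
`siPer1Per2` use $e = 0.8$.

What the generator does **not** emulate: single-cell desynchronization as a
mechanism (damping is imposed, not emergent), well-to-well coupling,
luciferin depletion kinetics, temperature effects, or non-Gaussian outliers
such as plate-reader glitches. Passing tests therefore validate the
*analysis* under the stated signal class, not the biology of any particular
cell line.

# Numerical behaviour and known limitations

**Damping bias.** The fitted model is deliberately a *constant-amplitude*
sinusoid (the damping lives only in the simulator), so damped inputs yield
$R^2 < 1$ by design — and, less obviously, a small period bias: fitting a
constant-amplitude sinusoid to $e^{-\lambda t}\sin(\omega t)$ over a finite
window shifts the SSE minimum by an amount that oscillates with the
fractional number of cycles covered and with phase. At $\lambda = 0.01$/h
over 72 h the noiseless bias reaches $\pm 0.18$ h at the least favourable
periods in 22–30 h, and de-trending adds a further phase-twist contribution
(the running mean of a *damped* sinusoid acquires a complex gain) of up to
$\sim 0.1$ h. Combined with the noise floor at signal-to-noise 5 (period sd
0.08–0.14 h), roughly 80% — not all — of single-well period estimates land
within $\pm 0.2$ h of truth in the package's recovery experiment (200
simulated wells, truths uniform in 22–30 h; `scripts/acceptance.R`
recomputes this rate). Condition means inherit the bias because
synchronized replicates share a common phase. Users comparing conditions
should therefore rely on *contrasts* between conditions measured under the
same protocol, which the bias largely cancels, rather than absolute period
values at the 0.1-h scale.

**Null-score inflation.** Smoothing concentrates the noise that survives it
in the low-frequency band, so the best-fitting sinusoid to a *rhythm-free*
smoothed trace attains $R^2 \approx 0.2$, versus $\lesssim 0.05$ without
smoothing. Rhythmic wells at the default noise level score $> 0.9$, so the
separation remains wide, but $R^2$ thresholds for calling a well rhythmic
must be calibrated for the preprocessing actually applied.

**Degenerate inputs.** Constant traces produce degenerate fits ($R^2 = 0$,
amplitude 0) and are excluded from condition means but counted and logged.
Periods shorter than twice the sampling interval make the design matrix
rank-deficient; this raises an explicit error rather than returning an
aliased fit.

**Problem sizes.** The validation suite runs at the recording's native
scale: 361 timepoints per well, plates of 3–24 wells, 50-instance
oracle-equivalence checks against a 0.001-h dense grid, and 200-simulation
recovery experiments — sizes at which every check completes in seconds to a
couple of minutes on a laptop.

# Per-well fits versus fitting the averaged curve

Replicate-averaged curves (the common display format) and per-well fits
answer slightly different questions. The pipeline's default fits each well
separately and aggregates parameters as mean ± SEM, which yields dispersion
estimates and flags individual degenerate wells. `runPipeline(...,
fit_mean = TRUE)` additionally fits each condition's replicate-averaged
trace for parity with published figure panels. For synchronized technical
replicates the two agree closely; for desynchronized wells ensemble
averaging attenuates the oscillation (24 wells with phases uniform over the
cycle retain under 30% of single-well amplitude) and the averaged-curve fit
is then not a rhythmicity measure of the individual wells.

# A worked example

```{r example, eval = FALSE}
plate <- simulatePlate(scenarioPreset("MC38", n_wells = 12, seed = 7))
res <- runPipeline(plate)
res$summaries
#>   condition n_wells n_converged period_mean_h period_sem_h amplitude_mean
#> 1      MC38      12          12      26.66153   0.06797035       60.48319
#>   amplitude_sem   r2_mean      r2_sem
#> 1     0.6642728 0.9428853 0.003098839
```

The condition mean lands near the preset's 26.3-h period (the ~0.3-h excess
is the damping bias discussed above, at the preset's damping of 0.015/h),
with well-to-well SEM of ~0.07 h, and a mean rhythmicity score of 0.94.
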