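# LumiRhythm

Rhythmicity analysis of plate-format bioluminescence reporter recordings.

Cells carrying a circadian luciferase reporter (e.g. Per2::luc) are
synchronized with a dexamethasone pulse and recorded in a plate luminometer
every 12 minutes for several days. Each well's trace is a ~24-h oscillation
riding on a large decaying baseline, plus technical noise. LumiRhythm turns
such recordings into per-well and per-condition rhythm parameters:

1. **De-trend** — subtract a centered 24-h running mean (removes
   proliferation/signal-decline baseline);
2. **Smooth** — a centered 2-h running mean (removes technical noise);
3. **Fit** — period-profiled least squares of the model
   *y(t) = c + A·sin(2π(t − φ)/T)*: an exact OLS solve at each candidate
   period T, a coarse SSE scan over 16–40 h, then golden-section
   refinement. Reported per well: period T (h), amplitude A (counts, gain
   calibrated back to the unfiltered signal), phase φ (h, first ascending
   zero-crossing), constant level c, and R² = 1 − SSE/SST as the
   rhythmicity score;
4. **Aggregate** — per-condition mean ± SEM with degenerate /
   non-converged wells excluded from means but counted and logged.

A synthetic-plate generator (damped sinusoid on a decaying baseline, phase
jitter/diffusion, Gaussian noise; presets for the MC38 / E0771 / LLC cancer
lines at their reported periods 26.3 / 27.2 / 28.3 h, NIH3T3 fibroblasts,
and siRNA knockdown scenarios) makes the whole pipeline testable end to end
without any external data. Small study metrics (caliper tumor volume
V = W²·L/2, organ/body weight ratio) are included.

## A worked example

```r
library(LumiRhythm)

plate <- simulatePlate(scenarioPreset("MC38", n_wells = 12, seed = 7))
res <- runPipeline(plate)
res$summaries
#>   condition n_wells n_converged period_mean_h period_sem_h amplitude_mean
#> 1      MC38      12          12      26.66153   0.06797035       60.48319
#>   amplitude_sem   r2_mean      r2_sem
#> 1     0.6642728 0.9428853 0.003098839
```

Twelve simulated MC38-like wells (true period 26.3 h, signal-to-noise 5)
yield a condition mean of 26.66 ± 0.07 h and a mean rhythmicity score
R² = 0.94. The ~0.3-h excess over the true period is the documented damping
bias of fitting a constant-amplitude sinusoid to a damped oscillation (see
the vignette, "Numerical behaviour and known limitations"); condition
*contrasts* cancel it largely, and the cell-line ordering
MC38 < E0771 < LLC is reproduced robustly.

Per-well results live in `res$fits`; `writeFitReport(res, "report/")`
writes deterministic CSV/YAML reports. `readPlate()` / `writePlate()`
define the on-disk dialect: a wide CSV (`time_h,<well>,...`) plus a YAML
sidecar mapping wells to conditions and replicates. A thin CLI over these
functions is in `inst/scripts/lumirhythm.R`
(`simulate` / `fit` / `report`).

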