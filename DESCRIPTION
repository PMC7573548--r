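Package: LumiRhythm
Title: Rhythmicity Analysis of Bioluminescence Reporter Recordings
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for circadian rhythmicity analysis of plate-format
    luciferase reporter recordings (e.g. Per2::luc LumiCycle traces).
    Provides de-trending and moving-average denoising of raw traces, a
    period-profiled least-squares fit of a constant-plus-sinusoid model
    yielding period, amplitude, phase and an R-squared rhythmicity score,
    per-condition aggregation (mean +/- SEM), and a synthetic-plate
    generator emulating dexamethasone-synchronized, exponentially damped
    oscillations on decaying baselines for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: TimeCourse, Regression, Preprocessing, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'LumiRhythm-package.R'
    'accessors.R'
    'rhythm-fit.R'
    'preprocess.R'
    'pipeline.R'
    'simulate.R'
    'trace-io.R'
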