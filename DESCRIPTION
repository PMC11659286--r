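Package: pneumotrace
Title: Cardiorespiratory Waveform Simulation, Segmentation, and Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing rodent cardiorespiratory recordings from
    whole-body barometric plethysmography and neonatal pneumotachography.
    Detects breaths and heartbeats from raw pressure/flow traces, flags calm
    breaths, calls apneas and sighs with relative-threshold definitions,
    segments adult gas-challenge sessions into chemoreflex epochs with
    flow-through respirometry (VO2) normalisation, scores neonatal
    autoresuscitation trials (apnea induction, gasping, heart-rate and
    ventilatory recovery latencies, cardiorespiratory decoupling, survival),
    and fits the accompanying linear mixed-effects models with Tukey HSD
    contrasts. A seeded synthetic-trace generator with analytic ground truth
    supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    withr,
    readr,
    ggplot2,
    generics,
    signal,
    stats,
    utils,
    lme4,
    lmerTest,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
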