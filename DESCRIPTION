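Package: chronoVigil
Title: Simulation and Analysis of Vigilance-Related Brain Activation
    Anchored to Circadian and Homeostatic Sleepiness
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to simulate and analyse a chronobiological neuroimaging
    study in which event-related BOLD responses during a psychomotor
    vigilance task are anchored to the 24-h time course of subjective
    sleepiness under 40-h sleep deprivation and 40-h multiple-nap
    protocols. Provides a synthetic-cohort generator with known ground
    truth (two-process sleepiness model with circadian-homeostatic
    interaction, reaction-time and lapse simulation, event-related BOLD
    forward model over a labelled toy brain, nap hypnograms with
    circadian REM modulation, and sleep-EEG spectra with delta-power
    rebound), behavioural summaries and reaction-time partitioning,
    sleep-derived homeostatic and circadian covariates, first-level
    GLM estimation with canonical HRF convolution, sleepiness-anchored
    parametric contrasts, and second-level permutation-based
    family-wise-error inference with ROI small-volume correction,
    exclusive masking and peak tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
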