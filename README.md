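# chronoVigil

Simulation and analysis of vigilance-related brain activation anchored
to the 24-h time course of subjective sleepiness.

Sleepiness over a 40-h protocol is governed by the two-process model:
homeostatic sleep pressure S(t) (saturating rise during wakefulness,
fast decay during naps) and a circadian process
C(t) = cos(2π(t − φ)/24), combined here as

    L(t) = k0 + kS·S(t) + kC·C(t) + kSC·S(t)·C(t)

so that circadian modulation is amplified under high sleep pressure.
Comparing a 40-h sleep-deprivation arm (SD) with a 40-h multiple-nap
arm (NP; 10 × 160 min wake / 80 min nap) separates the two processes.
The package implements the corresponding neuroimaging analysis: for
each subject, event-related GLM fits of in-scanner psychomotor
vigilance task (PVT) sessions at 5, 13, 21, 29 and 37 h after wake-up,
split by reaction-time range (fast < 25th percentile, slow > 75th,
lapses > 500 ms); then *anchored contrasts* — across-session weighted
sums whose weights are the z-scored group-mean KSS sleepiness profile
(z(SD) on SD, z(NP) on SD and NP, and the re-centred difference
z(SD) − z(NP) as a near-linear homeostatic slope) — tested at the
group level with one-sample sign-flip permutation maxT inference
(voxel-level FWE), ROI small-volume correction, exclusive masking
between speed ranges, and peak tables. Sleep-derived covariates
(NREM 0.7–4 Hz delta-power rebound between recovery and baseline
nights; a composite circadian sleep-wake-promotion score from nap REM
peaks and evening-nap wakefulness) enter ANCOVA-style slope tests.

Because no public data exist for this design, the package ships a
fully synthetic cohort generator with planted ground truth for every
stage — two-process KSS ratings, PVT event streams, 4D BOLD series
over a labelled toy brain, nap hypnograms with circadian REM
modulation and a wake-maintenance-zone evening nap, and sleep-EEG
spectra with subject-specific delta rebounds — so the entire analysis
is verifiable end to end. See `vignettes/anchored-vigilance.Rmd` for
the models, calibration and design decisions.

## Worked example

```r
library(chronoVigil)

coh <- simulateCohort(8, seed = 42)
coh
#> Cohort of 8 subjects (seed 42 )
#>   KSS ratings: 80 session records; 80 nap records
#>   PVT trials: 4887
#>   EEG subjects: 8

sleepinessProfile(coh, "SD")
#> SleepinessProfile (SD)
#>   mean KSS: 5.31, 5.12, 7.00, 6.50, 5.56
#>   z-weights: -0.810, -1.069,  1.517,  0.827, -0.465
```

The SD profile peaks at the 21-h session (biological night) and stays
elevated on the second day; its z-weights are the anchor for the first
contrast. Partitioning one subject's night-session reaction times:

```r
pvt <- pvtTrials(coh)
rts <- subset(pvt, subject == 1 & condition == "SD" & session == 3 &
                   trial_type == "clock")
part <- partitionRts(rts$response_time_ms)
table(part$labels)
#>         fast intermediate         slow        lapse
#>            7           13            7            9
round(c(part$p25, part$p75), 1)
#> [1] 282.6 323.5
```

Seven fast events and nine lapses at the night session of a sleepy
subject. The sleep markers (here with a shortened simulated night to
keep the example quick):

```r
mt <- markerTable(coh, cohortConfig(eeg = list(nEeg = 8L,
        epochsPerNight = 120L,
        nightMix = c(W = 5L, N1 = 10L, N2 = 55L, N3 = 25L, N4 = 10L,
                     R = 15L)))$eeg)
mt[, c("subject", "delta_rebound", "circ_strength", "excluded")]
#>   subject delta_rebound circ_strength excluded
#> 1       1          30.9         122.6    FALSE
#> 2       2         123.5          86.2    FALSE
#> ...
#> 5       5            NA          98.7     TRUE   # planted gross outlier,
#>                                                  # flagged by the 2-IQR rule
```

Subject 5 is the planted gross-negative rebound outlier; it is excluded
from covariate analyses exactly as the two-IQR rule dictates. The whole
pipeline — simulation, behaviour, markers, first-level GLMs, anchored
contrasts, permutation group inference, report — runs as

```r
runPipeline("out/", "all", nSubjects = 8, seed = 1, nPerm = 500)
```

or from a shell via `inst/scripts/chronovigil.R`. Each stage writes
plain-text/NIfTI artifacts plus a manifest; re-running a stage
reproduces its outputs bit-identically.

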