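---
title: "Anchoring vigilance-related brain activation to the 24-h sleepiness time course: models and design choices"
author: "chronoVigil"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package addresses

Subjective sleepiness over a 40-h constant-routine protocol is shaped by
two interacting processes: homeostatic sleep pressure (process S, rising
with time awake) and the circadian drive (process C, an approximately
24-h oscillation). Under total sleep deprivation (SD) both act together;
under a multiple-nap protocol (NP; ten cycles of 160 min wakefulness and
an 80-min nap opportunity) the naps keep S low and the circadian
component is seen in near isolation. `chronoVigil` implements the
analysis that asks *where in the brain event-related BOLD activation
during a psychomotor vigilance task (PVT) follows the group-mean time
course of sleepiness* across five scan sessions at 5, 13, 21, 29 and
37 h after habitual wake-up, separately for optimal (fast) and
non-optimal (slow) reaction times — together with a fully synthetic
cohort generator so that every stage of the analysis can be validated
against planted ground truth without access to any human data.

The four across-session contrasts are anchored contrasts: the z-scored
group-mean Karolinska Sleepiness Scale (KSS) profile of an arm is used
as the weight vector over that subject's five session contrast volumes:

1. **CxS_SD** — z(SD profile) on SD sessions: the circadian-by-
   homeostatic interaction pattern.
2. **C_on_SD** — z(NP profile) on SD sessions: a circadian pattern
   under high sleep pressure.
3. **C_on_NP** — z(NP profile) on NP sessions: a circadian pattern
   under low sleep pressure.
4. **S_minus_C_SD** — z(SD) − z(NP), re-centred, on SD sessions: the
   near-linear homeostatic slope left after removing the circadian
   shape.

Each contrast is tested in both directions (T+/T−) with one-sample
permutation (sign-flip) maxT inference, voxel-level FWE-corrected.

## The two-process sleepiness generator

The latent sleepiness of subject *i* at elapsed time *t* is

  L(t) = k0 + kS·S(t) + kC·C(t) + kSC·S(t)·C(t)

with the classic saturating-exponential homeostat
(S rises toward 1 during wake with time constant `tauRise`, decays
toward 0 during naps with `tauDecay`) and a cosine circadian process
`C(t) = circAmp · cos(2π(t − circPhase)/24)` whose acrophase
`circPhase` is the elapsed hour of maximal circadian sleepiness. The
multiplicative S·C term is essential: it amplifies circadian modulation
under high sleep pressure, which is the phenomenon the SD-anchored
contrast is designed to detect.

Defaults were calibrated **once** and then frozen:
`tauRise = 12 h`, `tauDecay = 1.2 h`, `S0 = 0.20`,
`circPhase = 23.5 h`, `kC = 0.55`, `kSC = 0.35`, and `kS`, `k0` solved
exactly so the noise-free group means equal the canonical grand-mean
KSS values of 5.7 (SD) and 4.3 (NP). The calibration was constrained
so that (i) the SD latent peaks at the 21-h session and stays elevated
through day 2, (ii) the NP latent peaks at the 21-h session, and
(iii) the difference of z-scored profiles z(SD) − z(NP) is *strictly
monotone* across sessions — the property that makes the fourth
contrast a clean homeostatic slope. Within the pinned functional form,
joint satisfaction of these constraints forces a fast-saturating
homeostat and implies a small dip of the SD latent at the 13-h session
relative to 5 h: the second session falls in the evening
wake-maintenance zone (WMZ), where circadian wake promotion transiently
outweighs the still-moderate sleep pressure. We regard this dip as a
defensible feature, not a bug; the hard ordering properties (21 h above
5 h, non-increasing from session 3 to 4) always hold.

Ratings are generated as the latent plus Gaussian rating noise
(SD 0.6 KSS), rounded to the integer 1–9 scale, twice per session
(pre-/post-scan) and around every nap. Because the scale is censored at
9, the observed grand mean sits slightly below the latent mean; the
frozen `k0` includes a small one-off compensation for this censoring.
Between-subject heterogeneity (intercept SD 0.35 KSS, circadian
amplitude SD 0.12, phase SD 0.75 h, S0 SD 0.04) was chosen so that
group profile estimates at n = 31 are stable; real cohorts are more
variable, so passing calibration here does not certify the pipeline
against human-scale between-subject noise.

## PVT simulation

Trial timing follows the in-scanner task: uniform 2–10 s
inter-stimulus intervals, 25 % null events of 2–10 s duration, a 1-s
feedback display, and a fixed 1.3-s post-trial fixation which sets the
trial yield of a 10-min session to ≈ 45 clock trials. Per trial a lapse
(RT > 500 ms) occurs with probability `plogis(lapseA + lapseB·L)`;
non-lapse RTs are shifted log-normal, truncated below the lapse
criterion, with a median that is logistic in L. All coefficients were
calibrated once against the canonical per-session fast-event and lapse
counts (≈ 8.3 fast events at session 3, ≈ 13.3 lapses at session 4 of
SD) and frozen.

Two honest limitations follow from the monotone-in-L design. The
canonical counts place more lapses at session 4 than at session 3
while sleepiness is higher at session 3; a lapse probability monotone
in sleepiness cannot reproduce that inversion, so the calibration
targets the session-4 lapse count and the session-3 fast count jointly,
which forces a shallow lapse slope (`lapseB = 0.2`). As a consequence
the generator's lapse counts vary less across sessions, and NP-arm
lapse counts are higher, than the canonical values. Neither quantity is
an anchor.

## Hypnograms, REM and the composite circadian-strength score

Each 80-min nap opportunity is realised as 160 thirty-second epochs.
Wakefulness within a nap follows a logistic model with a homeostatic
term, a circadian night term, and a sharp Gaussian wake-maintenance
zone term centred on the first-day evening nap (15.3 h elapsed).
A single sinusoid cannot simultaneously place maximal sleepiness in the
late night and maximal inability to sleep in the early evening; the
WMZ is physiologically a narrow, distinct phenomenon, so it gets its
own term. The WMZ term is amplified by the subject's latent circadian
sleep-wake-promotion strength.

The REM fraction of sleep oscillates with an acrophase of 25.5 h
(late night/early morning), is amplified by the same circadian-strength
latent, is coupled to the subject's latent sleepiness at nap time, and
carries a protocol-progression term (REM pressure accumulating across
the protocol) — without the latter the first morning nap, which sits at
the same clock phase as the late-protocol morning naps, would tie with
them for the REM peak. The pooled correlation between per-nap REM
amount and nap-adjacent sleepiness ratings lands near the canonical
Spearman r ≈ 0.4 by this construction.

The composite circadian-strength score is the maximum over naps of REM
epochs as a percentage of sleep epochs, plus the percentage of wake
epochs in the evening nap. The two terms are deliberately both
expressed as percentages of their own denominators so they are
commensurate before summation.

## Sleep EEG and the delta-power rebound

Whole nights (960 epochs of 30 s, 64 Hz) are simulated per epoch as
white noise plus a delta oscillation placed on an exact frequency bin
(0.8–3.5 Hz), with band power scaled by stage (N3/N4 > N2 > N1) such
that the artifact-free NREM mean of 0.7–4 Hz power equals the
subject's planted value exactly in expectation: baseline nights carry
`deltaBaselineTrue`, recovery nights add the planted rebound. Spectra
are Hanning-windowed periodograms normalised as
`S[k] = 2|DFT(w·x)[k]|² / (Σw)²` with **no** equivalent-noise-bandwidth
correction; under this convention an on-bin tone of amplitude *a*
contributes exactly 0.75 a² over its three-bin main lobe, which the
test suite checks in closed form. Because the white-noise floor inside
the band is identical for both nights, it cancels exactly in the
rebound (recovery − baseline), making the estimator unbiased by
construction. Band membership is decided by bin centre with inclusive
0.7 and 4 Hz edges. Epochs whose RMS amplitude exceeds 5× the median
RMS are treated as artifacts (2 % of epochs are planted as such) and
excluded. One cohort subject is planted with a grossly negative rebound
and is flagged by the two-IQR-below-the-25th-percentile rule
(linear-interpolation percentiles), reproducing the exclude-one
pattern; by default 26 of 31 subjects carry usable EEG.

## BOLD forward model and planted ground truth

The toy brain is a 20×24×20 grid of 3-mm isotropic voxels with an
MNI-like RAS affine centred mid-volume and six axis-aligned block
regions (thalamus, putamen, postcentral, parietal, lingual, frontal)
specified as fractions of the grid, so the same anatomy scales to any
grid size. Voxel series are baseline (100) + linear drift +
HRF-convolved event responses + a motion-coupled nuisance + stationary
AR(1) Gaussian noise (ρ = 0.3, marginal SD 3 % of baseline). Event
responses use the same canonical double-gamma HRF and microtime
convolution as the analysis design, so noise-free forward simulations
are recovered by the GLM to machine-level accuracy (the drift is set to
zero for those exactness checks, since a linear drift is only
approximately spanned by the discrete-cosine high-pass set).

The planted session-amplitude profile is the component of the z-scored
SD latent profile orthogonal to the z-scored NP profile, normalised to
unit maximum. This choice is what gives the acceptance surface its
shape: effects along this profile are detected by the SD-anchored
contrast (projection 1.85) and by the homeostatic-slope contrast, while
their projection onto the circadian (NP-derived) weights is exactly
zero — so contrasts (2) and (3) are true negatives up to the sampling
noise of the measured weights. Default amplitudes (percent signal
change, fast range, SD arm only): thalamus +0.9, putamen +0.5,
postcentral −0.48, parietal −0.42, frontal −0.42, lingual −0.42, plus a
sparser lingual −0.28 in the slow range. The asymmetry (stronger
thalamus, weaker cortex) was set during the one-off SNR calibration:
cortical amplitudes are the lever on false detections of the circadian
contrasts (sampling error of the measured NP weights projects onto
whatever is planted), whereas the thalamic amplitude governs the
surviving-peak rate under exclusive masking. Subject-level gains vary
(SD 0.15); the frontal amplitude is additionally modulated by the
subject's standardised delta-rebound latent and the putamen by the
circadian-strength latent (coupling 0.8, clamped at ±2.5), providing
ground truth for the covariate (ANCOVA-style) analyses. Nothing is
planted in the NP arm.

## Analysis choices

* **Percentiles** are computed by linear interpolation between order
  statistics (R type 7) throughout — RT partitioning and the outlier
  rule depend on this convention. Lapses are excluded before the
  25th/75th percentiles are computed; the lapse label takes precedence.
* **First-level estimation is OLS**, not prewhitened GLS: with AR(1)
  noise OLS is unbiased, merely mildly inefficient, and group inference
  is permutation-based, so first-level variance estimates never enter a
  parametric null. Residual variance uses the correct OLS degrees of
  freedom.
* **Design**: one main regressor per present speed range (fast,
  intermediate, slow, lapse) plus a mean-centred first-order
  time-modulation regressor per range (dropped with a message when a
  range has a single trial and the column degenerates to zero), six
  standardised motion parameters, a discrete-cosine high-pass set with
  128-s cutoff, and an intercept. Null events and the feedback display
  generate no predicted signal.
* **Smoothing** (8-mm FWHM Gaussian, edge-renormalised) is applied to
  the session contrast volumes rather than the time series; for a
  voxelwise linear model the two orders are algebraically identical,
  and this order is far cheaper.
* **Group inference** is one-sided permutation maxT: sign-flipping for
  one-sample tests, covariate permutation for slope tests, with
  p(v) = (1 + #{perm maxT ≥ t(v)})/(nPerm + 1); when fewer than nPerm
  distinct sign patterns exist the full set is enumerated (n = 4 gives
  16 patterns and a minimum achievable p of 1/16 — nothing can be
  significant at 0.05, which is the correct behaviour). Permutation
  maxT replaces random-field-theory FWE: at desk scale it is exact by
  construction and needs no smoothness estimation.
* **Exclusive masking** removes from a speed range's map all voxels
  exceeding an uncorrected same-direction p < 0.05 in the other range's
  map before peak listing; surviving FWE peaks are flagged
  speed-specific. The threshold is interpreted as uncorrected.
* **Peak tables** list 26-neighbourhood local maxima with FWE p ≤ α,
  labelled by atlas region, hemisphere from the sign of the x mm
  coordinate (x = 0 is bilateral), mm coordinates via the affine, and a
  Z column equal to the standard-normal quantile of the t tail
  probability (computed on the log scale for stability). Rows are
  ordered by p, ties broken by descending |t|.
* **Missing sessions**: a subject's gapped profile is included when its
  Pearson correlation with the group reference over shared sessions is
  significant (one-sided, α = 0.05, ≥ 3 shared sessions); anchored
  contrasts then re-standardise the weights over available sessions
  instead of imputing maps.

## Validation scales

The test suite validates the study conditions at sizes chosen to keep a
complete run on one CPU comfortable: behavioural and marker calibration
at the full n = 31 default; FWER calibration on 1000 null cohorts of
n = 8 over a 12³ grid with 500 permutations (empirical FWER 0.047);
pattern recovery on 20 seeded cohorts of n = 16 over a 12×14×12 grid
with 500 permutations. At that scale the planted pattern — thalamic T+
and cortical T− for the SD-anchored fast-range contrast, nothing for
the circadian contrasts, an extended cortical T− for the
homeostatic-slope contrast, and a fast-specific thalamic peak after
exclusive masking — is recovered in ≥ 18 of 20 cohorts with at most one
circadian-contrast false alarm. "Detection" for the circadian
contrasts is counted within the planted/reported regions; chance-level
single-voxel false positives anywhere in the volume are the 5 % FWE
property, which the FWER calibration tests separately.

## What passing these tests does and does not show

The generator is born aligned: there is no head motion in the images
(motion exists only as nuisance regressors), no spatial normalisation
error, no physiological noise structure beyond AR(1), no
scanner drift other than linear, and hypnograms are inputs rather than
scored signals. Rating censoring, the shallow lapse logistic, and the
smaller-than-human between-subject variability are documented above.
Passing the suite therefore certifies the statistical machinery —
estimators, contrasts, permutation control, exclusion rules — under a
known truth, not the robustness of the pipeline to the artefacts of
real acquisitions.

## Reproducibility

Every random quantity descends from one master seed through stable
string-keyed child seeds; regenerating a cohort with the same seed and
configuration is bit-identical, and BOLD series and EEG spectra are
materialised lazily from seeds stored in the cohort, so they never need
to be kept in memory or on disk to be reproducible. Pipeline stages
write manifests (seed, config hash, artifact checksums) and rebuild
their inputs from the upstream manifests, so any stage can be re-run
bit-identically in isolation.
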