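#' Default BOLD forward-model coefficients
#'
#' The forward model mirrors the analysis GLM: voxel time series are
#' baseline plus linear drift plus HRF-convolved event responses with
#' region-specific, session-specific amplitudes (percent signal change
#' of the 100-unit baseline), plus a motion-coupled nuisance component
#' and stationary AR(1) Gaussian noise. The default noise level was
#' calibrated once so that planted-effect recovery by the full
#' anchored-contrast analysis sits near, but not at, ceiling.
#'
#' @return Named list of coefficients.
#' @export
defaultBoldCoeffs <- function() {
  list(tr = 2.2, nScans = ceiling(600 / 2.2), baseline = 100,
       sigmaNoise = 3, ar1 = 0.3, driftAmp = 1.0,
       motionStepSd = 0.02, motionCoupling = 0.3,
       subjectGainSd = 0.15, smoothFwhm = 8,
       reboundCoupling = 0.8, circCoupling = 0.8, modClamp = 2.5)
}

#' Default planted region-by-session effect profiles
#'
#' Ground-truth activation profiles over the five SD sessions, in
#' percent signal change per region and speed range. The base profile
#' is the component of the z-scored SD sleepiness profile orthogonal to
#' the z-scored NP profile (rising through the night, staying elevated
#' on the second day): effects aligned with it are detectable by the
#' SD-anchored contrast while projecting to zero onto the circadian
#' (NP-derived) weights. Arousal-related subcortical regions (thalamus,
#' putamen) activate along the profile during optimal (fast)
#' responses; task-related cortical regions follow its negative.
#' Nothing is planted in the NP arm.
#'
#' @return data.frame with columns region, speed, condition and the
#'   five session amplitudes \code{s1..s5}.
#' @export
defaultPlantedEffects <- function() {
  ph <- plantedProfile()
  mk <- function(region, speed, a, modulator = "none") {
    d <- data.frame(region = region, speed = speed, condition = "SD",
                    modulator = modulator)
    d[paste0("s", 1:5)] <- as.list(a * ph)
    d
  }
  rbind(mk("thalamus", "fast", 0.9),
        mk("putamen", "fast", 0.5, "circ"),
        mk("postcentral", "fast", -0.48),
        mk("parietal", "fast", -0.42),
        mk("frontal", "fast", -0.42, "rebound"),
        mk("lingual", "fast", -0.42),
        mk("lingual", "slow", -0.28))
}

# Unit-normalised SD-specific session profile: z(SD latent) with its
# projection on z(NP latent) removed, scaled to max |.| = 1.
plantedProfile <- function() {
  p <- defaultSubjectParams()
  zsd <- zpop(latentSleepiness(p, protocolSchedule("SD")))
  znp <- zpop(latentSleepiness(p, protocolSchedule("NP")))
  ph <- zsd - sum(zsd * znp) / sum(znp^2) * znp
  ph / max(abs(ph))
}

#' Simulate one BOLD session over the toy brain
#'
#' Forward model for one subject/condition/session: the session's PVT
#' events are partitioned into speed ranges, each range's onset train
#' is convolved with the canonical HRF, and region amplitudes from the
#' planted-effect table (matching the condition and session) scale the
#' responses inside their atlas blocks. Baseline, linear drift, a
#' motion-coupled nuisance and AR(1) noise complete the series.
#'
#' @param pvt trial table of this session.
#' @param brain a \linkS4class{ToyBrain}.
#' @param planted planted-effect table
#'   (\code{\link{defaultPlantedEffects}} layout); rows whose region is
#'   not an atlas label raise an error.
#' @param session session index 1-5.
#' @param condition protocol arm of the session.
#' @param coeffs see \code{\link{defaultBoldCoeffs}}.
#' @param gain subject-specific multiplicative amplitude gain.
#' @param modFactors named multipliers for modulated planted rows
#'   (\code{rebound}, \code{circ}): subject-level coupling of planted
#'   amplitudes to the homeostatic and circadian marker latents.
#' @param seed integer seed.
#' @return List with \code{data} (scans x voxels), \code{brain},
#'   \code{tr}, \code{motion} (scans x 6) and \code{partition}.
#' @export
simulateBold <- function(pvt, brain, planted = defaultPlantedEffects(),
                         session = 1L, condition = "SD",
                         coeffs = defaultBoldCoeffs(), gain = 1,
                         modFactors = c(rebound = 1, circ = 1),
                         seed = 1L) {
  nScans <- coeffs$nScans
  tr <- coeffs$tr
  V <- prod(brain@dim)
  clock <- pvt[pvt$trial_type == "clock", ]
  part <- partitionRts(clock$response_time_ms)
  pl <- planted[planted$condition == condition, , drop = FALSE]
  bad <- setdiff(unique(pl$region), names(brain@labels))
  if (length(bad))
    stop("planted effect references unknown region label: ",
         paste(bad, collapse = ", "))
  # amplitude per voxel and speed range
  amp <- list()
  if (is.null(pl$modulator)) pl$modulator <- "none"
  for (i in seq_len(nrow(pl))) {
    ty <- pl$speed[i]
    a <- pl[[paste0("s", session)]][i] * gain
    if (pl$modulator[i] != "none")
      a <- a * modFactors[[pl$modulator[i]]]
    if (a == 0) next
    m <- regionMask(brain, pl$region[i])
    if (is.null(amp[[ty]])) amp[[ty]] <- numeric(V)
    amp[[ty]][m] <- amp[[ty]][m] + a
  }
  tEnd <- nScans * tr
  drift <- coeffs$driftAmp * ((0:(nScans - 1L)) * tr / tEnd - 0.5)
  Y <- matrix(coeffs$baseline + drift, nScans, V)
  for (ty in names(amp)) {
    sel <- part$labels == ty
    if (!any(sel)) next
    reg <- eventRegressor(clock$onset_s[sel], nScans, tr)
    Y <- Y + outer(reg, amp[[ty]])
  }
  withSeed(seed, {
    motion <- vapply(1:6, function(j)
      cumsum(stats::rnorm(nScans, 0, coeffs$motionStepSd)),
      numeric(nScans))
    if (coeffs$motionCoupling > 0) {
      m1 <- motion[, 1L]
      if (stats::sd(m1) > 0) m1 <- (m1 - mean(m1)) / stats::sd(m1)
      cv <- stats::rnorm(V, 0, coeffs$motionCoupling)
      Y <- Y + outer(m1, cv)
    }
    if (coeffs$sigmaNoise > 0) {
      rho <- coeffs$ar1
      E <- matrix(stats::rnorm(nScans * V, 0,
                               coeffs$sigmaNoise * sqrt(1 - rho^2)),
                  nScans, V)
      E[1L, ] <- E[1L, ] / sqrt(1 - rho^2)
      for (t in 2:nScans) E[t, ] <- E[t, ] + rho * E[t - 1L, ]
      Y <- Y + E
    }
    list(data = Y, brain = brain, tr = tr, motion = motion,
         partition = part)
  })
}

#' First-level session contrast maps for one subject and condition
#'
#' Materialises the five BOLD sessions of one subject/condition from
#' the cohort's stored seeds, fits the event-related GLM per session
#' and returns spatially smoothed session contrast volumes for the
#' requested speed range. (Smoothing is applied to the contrast
#' volumes; for a voxelwise linear model this is equivalent to
#' smoothing the time series first.)
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param subject subject id.
#' @param condition \code{"SD"} or \code{"NP"}.
#' @param speed \code{"fast"} or \code{"slow"}.
#' @param brain toy brain (defaults to the cohort's configured
#'   geometry).
#' @param planted planted-effect table.
#' @return List of five 3D contrast arrays.
#' @export
subjectSessionMaps <- function(cohort, subject, condition = "SD",
                               speed = "fast", brain = NULL,
                               planted = defaultPlantedEffects()) {
  subjectContrastMaps(cohort, subject, condition, speed, brain,
                      planted)[[speed]]
}

#' Session contrast maps for several speed ranges at once
#'
#' Like \code{\link{subjectSessionMaps}} but simulates and fits each
#' session once and extracts all requested speed ranges from the same
#' fit.
#'
#' @inheritParams subjectSessionMaps
#' @param speeds character vector of speed ranges.
#' @return Named list (per speed) of lists of five 3D arrays.
#' @export
subjectContrastMaps <- function(cohort, subject, condition = "SD",
                                speeds = c("fast", "slow"), brain = NULL,
                                planted = defaultPlantedEffects()) {
  cfg <- cohort@config
  if (is.null(brain))
    brain <- toyBrain(cfg$brain$dim, cfg$brain$voxelMm)
  coeffs <- cfg$bold
  i <- match(subject, cohort@subjects$subjectId)
  gain <- cohort@subjects$boldGain[i]
  clamp <- function(z) pmax(-coeffs$modClamp, pmin(coeffs$modClamp, z))
  zReb <- clamp((cohort@subjects$deltaReboundTrue[i] -
                 cfg$eeg$reboundMean) / cfg$eeg$reboundSd)
  zCirc <- clamp(cohort@subjects$circStrengthTrue[i])
  modFactors <- c(rebound = 1 + coeffs$reboundCoupling * zReb,
                  circ = 1 + coeffs$circCoupling * zCirc)
  out <- lapply(speeds, function(sp) vector("list", 5L))
  names(out) <- speeds
  for (ses in 1:5) {
    pvt <- cohort@pvt[cohort@pvt$subject == subject &
                      cohort@pvt$condition == condition &
                      cohort@pvt$session == ses, ]
    bl <- simulateBold(pvt, brain, planted, ses, condition, coeffs, gain,
      modFactors,
      seed = childSeed(cohort@seed,
                       paste0("bold-", subject, "-", condition, "-", ses)))
    fit <- fitGlm(bl, buildDesign(pvt, bl$partition, bl$motion,
                                  coeffs$tr, coeffs$nScans))
    for (sp in speeds)
      out[[sp]][[ses]] <- smoothVolume(sessionContrast(fit, sp),
                                       coeffs$smoothFwhm, brain@voxelMm)
  }
  out
}
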