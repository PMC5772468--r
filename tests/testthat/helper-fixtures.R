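# Shared fixtures: a small cohort and reduced geometries so unit tests
# stay fast; the acceptance suite uses the full study conditions.

smallBrainConfig <- function(...) {
  cohortConfig(brain = list(dim = c(12L, 14L, 12L), voxelMm = 3), ...)
}

# Memoised small cohorts (8 subjects) keyed by seed.
.cohortCache <- new.env(parent = emptyenv())
smallCohort <- function(seed = 1L, n = 8L) {
  key <- paste0("c", seed, "-", n)
  if (is.null(.cohortCache[[key]]))
    .cohortCache[[key]] <- simulateCohort(n, smallBrainConfig(), seed)
  .cohortCache[[key]]
}

# Noise-free BOLD coefficient set (forward model in the design span).
noiselessBold <- function() {
  co <- defaultBoldCoeffs()
  co$sigmaNoise <- 0
  co$motionCoupling <- 0
  co$driftAmp <- 0
  co
}

flatPlanted <- function(region = "thalamus", speed = "fast", amp = 1) {
  d <- data.frame(region = region, speed = speed, condition = "SD",
                  modulator = "none")
  d[paste0("s", 1:5)] <- as.list(rep(amp, 5))
  d
}

# A deterministic PVT session with a healthy mix of all event types.
fixturePvt <- function(latent = 6.5, seed = 7L) {
  tr <- simulatePvtSession(latent, seed = seed)
  cbind(subject = 1L, condition = "SD", session = 1L, tr)
}

profileFromMeans <- function(cond, means) {
  new("SleepinessProfile", condition = cond, meanKss = means,
      zWeights = zscoreProfile(means), nSubjects = rep(31L, 5L))
}

# Default-parameter latent profiles (the generator's calibrated group
# time courses).
latentProfiles <- function() {
  p <- defaultSubjectParams()
  list(sd = latentSleepiness(p, protocolSchedule("SD")),
       np = latentSleepiness(p, protocolSchedule("NP")))
}
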