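#' Default sleep-EEG simulation coefficients
#'
#' Whole-night EEG is simulated per 30-s epoch at 64 Hz as white
#' background noise plus a delta-band oscillation placed on an exact
#' frequency bin, whose band power is scaled by sleep stage (deeper
#' NREM, more slow-wave activity) so that the artifact-free NREM mean
#' of summed 0.7-4 Hz power equals the subject's planted night-level
#' value exactly in expectation. A configurable fraction of epochs is
#' replaced by high-amplitude artifacts.
#'
#' @return Named list of coefficients.
#' @export
defaultEegCoeffs <- function() {
  list(fs = 64, epochSec = 30, epochsPerNight = 960L,
       sigmaWhite = 30, stageWeight = c(W = 0.15, N1 = 0.4, N2 = 0.8,
                                        N3 = 1.6, N4 = 2.0, R = 0.15),
       restPower = 25, toneBinRange = c(24L, 105L),
       powerJitterShape = 25, artifactFraction = 0.02,
       artifactGain = 8,
       nightMix = c(W = 40L, N1 = 60L, N2 = 440L, N3 = 220L,
                    N4 = 80L, R = 120L))
}

#' Hanning-windowed power spectrum of one epoch
#'
#' Computes the one-sided windowed periodogram
#' \code{S[k] = 2 |DFT(w x)[k]|^2 / (sum w)^2} with a periodic Hanning
#' window, for bins k = 1 .. N/2 - 1 at resolution fs/N Hz. No
#' equivalent-noise-bandwidth correction is applied; a pure tone on bin
#' k0 contributes exactly \code{0.75 a^2} summed over its three-bin
#' main lobe (the package-wide band-power convention).
#'
#' @param x numeric signal vector.
#' @param fs sampling frequency (Hz).
#' @return List with \code{freq} (Hz) and \code{power}.
#' @export
hanningSpectrum <- function(x, fs) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)
  X <- stats::fft(w * x)
  k <- seq_len(n %/% 2 - 1L)
  list(freq = k * fs / n,
       power = 2 * Mod(X[k + 1L])^2 / sum(w)^2)
}

# A fixed whole-night stage sequence (NREM-REM cycling) realised from
# the configured stage totals; epoch order is irrelevant to the delta
# marker (tested), so the layout is a simple cycle template.
nightHypnogram <- function(coeffs = defaultEegCoeffs()) {
  mix <- coeffs$nightMix
  perCycle <- floor(mix / 5)
  cycleSeq <- unlist(lapply(seq_along(perCycle), function(i)
    rep(i, perCycle[i])))
  H <- rep(cycleSeq, 5)
  # pad with N2 to the exact epoch count
  pad <- coeffs$epochsPerNight - length(H)
  c(H, rep(3L, max(0L, pad)))[seq_len(coeffs$epochsPerNight)]
}

#' Simulate one night of sleep-EEG spectra
#'
#' Generates per-epoch Hanning power spectra for a baseline or recovery
#' night of the sleep-deprivation arm. The artifact-free NREM mean of
#' delta-band power equals \code{deltaBaselineTrue} (baseline) or
#' \code{deltaBaselineTrue + deltaReboundTrue} (recovery) in
#' expectation, on top of a white-noise floor common to both nights.
#'
#' @param params subject parameter list carrying
#'   \code{deltaBaselineTrue} and \code{deltaReboundTrue} (uV^2).
#' @param night \code{"baseline"} or \code{"recovery"}.
#' @param coeffs see \code{\link{defaultEegCoeffs}}.
#' @param seed integer seed.
#' @return List with \code{freq}, \code{power} (epoch x bin matrix),
#'   \code{stages} (stage codes), \code{rms} (per-epoch RMS amplitude)
#'   and \code{night}.
#' @export
simulateSleepEeg <- function(params, night = c("baseline", "recovery"),
                             coeffs = defaultEegCoeffs(), seed = 1L) {
  night <- match.arg(night)
  nightP <- params$deltaBaselineTrue +
    if (night == "recovery") params$deltaReboundTrue else 0
  if (is.na(nightP)) stop("subject has no planted delta-power values")
  n <- round(coeffs$fs * coeffs$epochSec)
  stages <- nightHypnogram(coeffs)
  nE <- length(stages)
  w <- coeffs$stageWeight[stageLevels[stages]]
  withSeed(seed, {
    artifact <- stats::runif(nE) < coeffs$artifactFraction
    nrem <- isNremCode(stages)
    # scale stage weights so clean NREM epochs average to the night value
    wbar <- mean(w[nrem & !artifact])
    target <- ifelse(nrem, nightP * w / wbar, coeffs$restPower)
    target <- pmax(target, 1)
    shp <- coeffs$powerJitterShape
    power <- NULL
    rms <- numeric(nE)
    for (e in seq_len(nE)) {
      a2 <- target[e] / 0.75 * stats::rgamma(1L, shp, shp)
      bin <- sample(seq(coeffs$toneBinRange[1L], coeffs$toneBinRange[2L]), 1L)
      tt <- (seq_len(n) - 1L) / coeffs$fs
      x <- sqrt(a2) * cos(2 * pi * (bin / coeffs$epochSec) * tt +
                          stats::runif(1L, 0, 2 * pi)) +
        stats::rnorm(n, 0, coeffs$sigmaWhite)
      if (artifact[e]) x <- x * coeffs$artifactGain
      sp <- hanningSpectrum(x, coeffs$fs)
      if (is.null(power))
        power <- matrix(0, nE, length(sp$power))
      power[e, ] <- sp$power
      rms[e] <- sqrt(mean(x^2))
    }
    list(freq = sp$freq, power = power, stages = stages, rms = rms,
         night = night)
  })
}
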