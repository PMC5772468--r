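#' Default nap sleep-architecture coefficients
#'
#' Naps are realised as 160 epochs of 30 s. Wakefulness within a nap
#' opportunity follows a logistic model combining homeostatic pressure
#' (more sleep pressure, less wake), a circadian night term (sleep
#' easiest during the biological night) and a sharp wake-maintenance
#' zone (WMZ) term centred on the first-day evening nap; the WMZ term
#' is amplified by the subject's latent circadian sleep-wake-promotion
#' strength. The REM fraction of sleep follows a circadian oscillation
#' peaking in the late night / early morning, also amplified by the
#' circadian-strength latent, and is coupled to the subject's latent
#' sleepiness at nap time.
#'
#' @return Named list of coefficients.
#' @export
defaultNapCoeffs <- function() {
  list(epochsPerNap = 160L,
       w0 = -1.2, wS = 1.2, wC = 0.8, wZ = 2.2, zG = 0.55,
       wmzCenter = 15.33, wmzWidth = 1.6,
       r0 = -1.9, rC = 0.5, rG = 0.4, rK = 0.18, rT = 0.6,
       remNoiseSd = 0.35, remPhase = 25.5,
       nremMix = c(N1 = 0.10, N2 = 0.55, N3 = 0.25, N4 = 0.10))
}

# Expected wake fraction and REM fraction (of sleep) for each nap of an
# NP schedule; deterministic given params. Used both by the generator
# and by tests of the propensity curves.
napPropensities <- function(params, sched, coeffs = defaultNapCoeffs()) {
  if (condition(sched) != "NP")
    stop("hypnograms are only defined for the NP schedule (no naps in SD)")
  nw <- napWindows(sched)
  mid <- rowMeans(nw)
  g <- params$circStrengthTrue
  if (is.na(g)) g <- 0
  S <- processS(params, sched, nw[, 1L])
  Cnight <- params$circAmp * cos(2 * pi * (mid - params$circPhase) / 24)
  wmz <- exp(-(mid - coeffs$wmzCenter)^2 / (2 * coeffs$wmzWidth^2))
  wakeFrac <- stats::plogis(coeffs$w0 - coeffs$wS * S - coeffs$wC * Cnight +
                            coeffs$wZ * (1 + coeffs$zG * g) * wmz)
  Crem <- params$circAmp * cos(2 * pi * (mid - coeffs$remPhase) / 24)
  lat <- latentSleepiness(params, sched, pmin(mid, 40))
  remFrac <- stats::plogis(coeffs$r0 +
                           coeffs$rC * (1 + coeffs$rG * g) * Crem +
                           coeffs$rK * (lat - 4.3) +
                           coeffs$rT * (mid / 40 - 0.5))
  data.frame(nap = seq_len(nrow(nw)), start = nw[, 1L], mid = mid,
             wakeFrac = wakeFrac, remFrac = remFrac)
}

#' Simulate nap hypnograms for one subject
#'
#' Draws stage labels for each 80-min nap opportunity of the NP
#' protocol (160 epochs of 30 s each) from the nap propensity model:
#' wake and REM epoch counts are binomial around their expected
#' fractions, non-REM epochs are split over stages N1-N4 by a fixed
#' mix, and stages are laid out as sleep-onset wake latency, a NREM
#' body, a late-nap REM block and terminal wake.
#'
#' @param params subject parameter list.
#' @param sched an NP \linkS4class{ProtocolSchedule}.
#' @param coeffs see \code{\link{defaultNapCoeffs}}.
#' @param seed integer seed.
#' @return Integer matrix nap x epoch with stage codes 1-6 mapping to
#'   \code{c("W", "N1", "N2", "N3", "N4", "R")} (attribute
#'   \code{stages}).
#' @export
simulateHypnograms <- function(params, sched, coeffs = defaultNapCoeffs(),
                               seed = 1L) {
  pro <- napPropensities(params, sched, coeffs)
  nE <- coeffs$epochsPerNap
  withSeed(seed, {
    H <- matrix(1L, nrow(pro), nE)
    for (j in seq_len(nrow(pro))) {
      nWake <- stats::rbinom(1L, nE, pro$wakeFrac[j])
      nSleep <- nE - nWake
      rf <- stats::plogis(stats::qlogis(pro$remFrac[j]) +
                          stats::rnorm(1L, 0, coeffs$remNoiseSd))
      nRem <- if (nSleep > 0L) stats::rbinom(1L, nSleep, rf) else 0L
      nNrem <- nSleep - nRem
      mix <- floor(coeffs$nremMix * nNrem)
      # keep the total exact; absorb rounding into N2
      mix["N2"] <- nNrem - sum(mix[c("N1", "N3", "N4")])
      latency <- ceiling(nWake * 0.6)
      tailWake <- nWake - latency
      stagesVec <- c(rep(1L, latency),
                     rep(2L, mix[["N1"]]), rep(3L, mix[["N2"]]),
                     rep(4L, mix[["N3"]]), rep(5L, mix[["N4"]]),
                     rep(6L, nRem), rep(1L, tailWake))
      H[j, ] <- stagesVec[seq_len(nE)]
    }
    attr(H, "stages") <- stageLevels
    H
  })
}
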