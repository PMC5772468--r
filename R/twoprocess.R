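#' Default subject parameters for the two-process sleepiness model
#'
#' The latent sleepiness model combines a homeostatic process S
#' (saturating exponential rise during wakefulness with time constant
#' \code{tauRise}, exponential decay during naps with \code{tauDecay},
#' asymptotes 1 and 0) with a circadian process
#' \code{C(t) = circAmp * cos(2*pi*(t - circPhase)/24)} whose acrophase
#' \code{circPhase} is the elapsed hour of maximal circadian sleepiness.
#' The latent is
#' \code{k0 + kS*S + kC*C + kSC*S*C};
#' the multiplicative S-by-C term amplifies circadian modulation under
#' high sleep pressure. Coefficients were calibrated once so that the
#' noise-free group profile reproduces the canonical grand-mean KSS
#' values of 5.7 (SD) and 4.3 (NP) and are fixed as package defaults.
#'
#' @return Named list of model parameters for one prototypical subject.
#' @examples
#' p <- defaultSubjectParams()
#' latentSleepiness(p, protocolSchedule("SD"))
#' @export
defaultSubjectParams <- function() {
  list(
    subjectId = 1L,
    S0 = 0.20, tauRise = 12, tauDecay = 1.2,
    circAmp = 1, circPhase = 23.5,
    k0 = 4.0216971296, kS = 2.3103801984, kC = 0.55, kSC = 0.35,
    # RT model: median (ms) and lapse probability are logistic in the
    # latent; calibrated once against printed per-session event counts.
    rt = defaultRtCoeffs(),
    deltaReboundTrue = NA_real_, deltaBaselineTrue = NA_real_,
    circStrengthTrue = NA_real_
  )
}

# Homeostatic process S along a schedule, evaluated at arbitrary elapsed
# times. Piecewise: saturating rise in wake, exponential fall in naps.
processS <- function(params, sched, times) {
  nw <- sched@napWindows
  rise <- function(s0, dt) 1 - (1 - s0) * exp(-dt / params$tauRise)
  fall <- function(s0, dt) s0 * exp(-dt / params$tauDecay)
  sAt <- function(t) {
    s <- params$S0
    tcur <- 0
    if (nrow(nw)) {
      for (i in seq_len(nrow(nw))) {
        if (t <= nw[i, 1L]) return(rise(s, t - tcur))
        s <- rise(s, nw[i, 1L] - tcur)
        if (t <= nw[i, 2L]) return(fall(s, t - nw[i, 1L]))
        s <- fall(s, nw[i, 2L] - nw[i, 1L])
        tcur <- nw[i, 2L]
      }
    }
    rise(s, t - tcur)
  }
  vapply(times, sAt, numeric(1))
}

# Circadian process C at elapsed times (unit-amplitude cosine scaled by
# the subject's circadian amplitude).
processC <- function(params, times) {
  params$circAmp * cos(2 * pi * (times - params$circPhase) / 24)
}

#' Latent sleepiness along a protocol
#'
#' Evaluates the noise-free two-process latent sleepiness for one
#' subject at the given elapsed times (default: the five scan sessions).
#'
#' @param params subject parameter list, see
#'   \code{\link{defaultSubjectParams}}.
#' @param sched a \linkS4class{ProtocolSchedule}.
#' @param times elapsed hours; must lie within the 40-h protocol.
#' @return Numeric vector of latent sleepiness values (KSS scale).
#' @export
latentSleepiness <- function(params, sched, times = sessionTimes(sched)) {
  stopifnot(is(sched, "ProtocolSchedule"))
  if (any(times < 0 | times > 40))
    stop("requested time outside the 40-h protocol schedule")
  S <- processS(params, sched, times)
  C <- processC(params, times)
  params$k0 + params$kS * S + params$kC * C + params$kSC * S * C
}

#' Simulate KSS ratings for one subject and protocol
#'
#' Draws pre- and post-scan Karolinska Sleepiness Scale ratings around
#' each session's latent sleepiness: two independent Gaussian rating
#' noises are added and the results rounded to the nearest integer,
#' clamped to the 1-9 scale.
#'
#' @inheritParams latentSleepiness
#' @param sigmaRating SD of the rating noise (KSS units).
#' @param seed integer seed.
#' @return data.frame with columns session, time_h, latent, pre, post.
#' @export
twoProcessKss <- function(params, sched, sigmaRating = 0.6, seed = 1L) {
  lat <- latentSleepiness(params, sched)
  withSeed(seed, {
    pre <- roundKss(lat + stats::rnorm(5L, 0, sigmaRating))
    post <- roundKss(lat + stats::rnorm(5L, 0, sigmaRating))
    data.frame(session = 1:5, time_h = sessionTimes(sched),
               latent = lat, pre = pre, post = post)
  })
}

roundKss <- function(x) pmin(9, pmax(1, round(x)))
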