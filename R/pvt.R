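#' Default reaction-time model coefficients
#'
#' The psychomotor vigilance task (PVT) model draws, per trial, a lapse
#' indicator with probability \code{plogis(lapseA + lapseB * latent)}
#' and, for non-lapse trials, a shifted log-normal reaction time whose
#' median \code{medBase + medGain * plogis(medSlope * (latent - medMid))}
#' increases with latent sleepiness (truncated below the 500-ms lapse
#' criterion; lapse RTs are 500 ms plus an exponential tail). Trial
#' timing follows the in-scanner task: uniform 2-10 s inter-stimulus
#' intervals, 25\% null events of 2-10 s duration, 1 s feedback display
#' and a fixed post-trial fixation. The coefficients and the
#' post-trial fixation (which sets the trial yield of the 10-min task)
#' were calibrated once against the canonical per-session fast-event
#' and lapse counts and are fixed as defaults.
#'
#' @return Named list of RT-model coefficients.
#' @export
defaultRtCoeffs <- function() {
  list(lapseA = -2.16, lapseB = 0.2,
       medBase = 230, medGain = 140, medSlope = 0.6, medMid = 5.8,
       sdlog = 0.30, shift = 150,
       lapseTailMean = 180, maxRt = 1800,
       isiRange = c(2, 10), nullFraction = 0.25, nullDurRange = c(2, 10),
       feedback = 1.0, postTrialGap = 1.3, duration = 600)
}

#' Simulate one 10-min in-scanner PVT session
#'
#' Generates the event stream of one session: clock events (requiring a
#' speeded response) interleaved with null events at random. Reaction
#' times above 500 ms are lapses by definition. RT location and lapse
#' probability are non-decreasing in latent sleepiness, and with a fixed
#' seed the per-trial random draws are coupled across latent values.
#'
#' @param latent latent sleepiness (KSS scale) driving the RT model.
#' @param rtCoeffs coefficient list, see \code{\link{defaultRtCoeffs}}.
#' @param seed integer seed.
#' @return data.frame with columns \code{onset_s}, \code{trial_type}
#'   (\code{"clock"} or \code{"null"}) and \code{response_time_ms}
#'   (NA for null events).
#' @examples
#' pvt <- simulatePvtSession(5.7, seed = 1)
#' mean(pvt$response_time_ms > 500, na.rm = TRUE)  # lapse fraction
#' @export
simulatePvtSession <- function(latent, rtCoeffs = defaultRtCoeffs(),
                               seed = 1L) {
  stopifnot(is.finite(latent))
  k <- rtCoeffs
  pLapse <- stats::plogis(k$lapseA + k$lapseB * latent)
  med <- k$medBase + k$medGain * stats::plogis(k$medSlope * (latent - k$medMid))
  meanlog <- log(med - k$shift)
  # probability mass of the shifted log-normal below the lapse criterion
  fCrit <- stats::plnorm(500 - k$shift, meanlog, k$sdlog)
  withSeed(seed, {
    onset <- numeric(0)
    type <- character(0)
    rt <- numeric(0)
    t <- 0
    repeat {
      # fixed draw layout per trial keeps streams coupled across latents
      u <- stats::runif(5L)
      isi <- k$isiRange[1L] + diff(k$isiRange) * u[1L]
      t0 <- t + isi
      if (t0 > k$duration) break
      if (u[2L] < k$nullFraction) {
        dur <- k$nullDurRange[1L] + diff(k$nullDurRange) * u[3L]
        onset <- c(onset, t0); type <- c(type, "null"); rt <- c(rt, NA_real_)
        t <- t0 + dur + k$postTrialGap
      } else {
        if (u[4L] < pLapse) {
          r <- 500 + stats::qexp(u[5L], 1 / k$lapseTailMean)
          r <- min(r, k$maxRt)
        } else {
          # inverse-CDF draw from the truncated shifted log-normal
          r <- k$shift + stats::qlnorm(u[5L] * fCrit, meanlog, k$sdlog)
        }
        onset <- c(onset, t0); type <- c(type, "clock"); rt <- c(rt, r)
        t <- t0 + r / 1000 + k$feedback + k$postTrialGap
      }
    }
    data.frame(onset_s = onset, trial_type = type, response_time_ms = rt)
  })
}
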