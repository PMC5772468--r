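#' NREM delta-band power of one night
#'
#' Mean, over artifact-free NREM epochs (stages N1-N4), of summed
#' spectral power across frequency bins whose centres lie in the
#' inclusive 0.7-4 Hz slow-wave band. Epochs whose RMS amplitude
#' exceeds 5 times the median RMS are treated as artifacts and
#' discarded.
#'
#' @param spectra per-epoch spectra as returned by
#'   \code{\link{simulateSleepEeg}} (fields \code{freq}, \code{power},
#'   \code{rms}).
#' @param stages stage codes aligned with the epochs (defaults to the
#'   stages carried by \code{spectra}).
#' @param band inclusive frequency bounds in Hz.
#' @param artifactFactor RMS multiple above which an epoch is rejected.
#' @return Delta power in uV^2.
#' @export
nremDeltaPower <- function(spectra, stages = spectra$stages,
                           band = c(0.7, 4), artifactFactor = 5) {
  if (length(stages) != nrow(spectra$power))
    stop("spectra epochs and hypnogram epochs are not aligned")
  nrem <- isNremCode(stages)
  clean <- spectra$rms <= artifactFactor * stats::median(spectra$rms)
  use <- nrem & clean
  if (!any(use)) stop("no artifact-free NREM epochs available")
  bins <- spectra$freq >= band[1L] & spectra$freq <= band[2L]
  mean(rowSums(spectra$power[use, bins, drop = FALSE]))
}

#' Delta-power rebound
#'
#' Recovery-night minus baseline-night NREM delta power, the marker of
#' homeostatic sleep pressure accumulated over sleep deprivation.
#'
#' @param baselinePower,recoveryPower NREM delta power (uV^2) of the
#'   two nights.
#' @return Rebound in uV^2.
#' @examples
#' deltaRebound(100, 160)  # 60
#' @export
deltaRebound <- function(baselinePower, recoveryPower) {
  recoveryPower - baselinePower
}

#' Flag low outliers by the 2-IQR rule
#'
#' Flags values lying more than two interquartile ranges below the 25th
#' percentile (linear-interpolation percentiles).
#'
#' @param values numeric vector (at least 5 values).
#' @return Logical vector, TRUE where flagged.
#' @examples
#' flagLowOutliers(c(1.0, 1.1, 1.2, 1.3, -5))
#' @export
flagLowOutliers <- function(values) {
  if (length(values) < 5L) stop("need at least 5 values")
  q1 <- pctl(values, 0.25)
  q3 <- pctl(values, 0.75)
  values < q1 - 2 * (q3 - q1)
}

#' Composite circadian sleep-wake-promotion score
#'
#' Sum of (i) the REM-sleep peak: the maximum over naps of REM epochs
#' as a percentage of total sleep epochs within that nap, and (ii) the
#' percentage of wake epochs in the nap scheduled in the evening of the
#' first day (the wake-maintenance zone). Both terms are percentages of
#' their respective denominators, making them commensurate.
#'
#' @param hypno integer nap x epoch stage matrix (codes 1-6, see
#'   \code{\link{simulateHypnograms}}).
#' @param sched the NP \linkS4class{ProtocolSchedule}.
#' @return Composite score (percent + percent).
#' @export
circadianStrength <- function(hypno, sched) {
  if (nrow(hypno) != nrow(napWindows(sched)))
    stop("hypnogram rows must match scheduled naps")
  remPct <- apply(hypno, 1L, function(e) {
    sleep <- sum(e != 1L)
    if (sleep == 0L) return(0)
    100 * sum(e == 6L) / sleep
  })
  ev <- eveningNapIndex(sched)
  wakePct <- 100 * sum(hypno[ev, ] == 1L) / ncol(hypno)
  max(remPct) + wakePct
}

#' Spearman correlation between REM amounts and sleepiness
#'
#' Rank correlation (with average-rank tie handling) and two-sided
#' p-value between per-nap REM sleep amounts and the sleepiness
#' ratings associated with the naps.
#'
#' @param remAmounts,kssValues paired numeric vectors (n >= 5).
#' @return List with \code{r} and \code{p}.
#' @export
remSleepinessCorrelation <- function(remAmounts, kssValues) {
  ok <- !is.na(remAmounts) & !is.na(kssValues)
  if (sum(ok) < 5L) stop("need at least 5 paired observations")
  x <- remAmounts[ok]; y <- kssValues[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rank correlation undefined for constant input")
  r <- stats::cor(x, y, method = "spearman")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(r = unname(r), p = unname(ct$p.value))
}

#' Per-subject homeostatic and circadian marker table
#'
#' Computes, for every subject with sleep-EEG data, the delta-power
#' rebound (recovery minus baseline night, SD arm) and, for every
#' subject, the composite circadian sleep-wake-promotion score from
#' the NP hypnograms; applies the 2-IQR low-outlier exclusion to the
#' rebounds. Excluded subjects carry no covariate value downstream.
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param eegCoeffs see \code{\link{defaultEegCoeffs}}.
#' @return data.frame with columns subject, delta_rebound,
#'   circ_strength, excluded, reason.
#' @export
markerTable <- function(cohort, eegCoeffs = defaultEegCoeffs()) {
  sub <- cohort@subjects
  npSched <- schedule(cohort, "NP")
  out <- data.frame(subject = sub$subjectId,
                    delta_rebound = NA_real_,
                    circ_strength = NA_real_,
                    excluded = FALSE, reason = "")
  for (i in seq_len(nrow(sub))) {
    p <- as.list(sub[i, ])
    hy <- cohortHypnogram(cohort, sub$subjectId[i])
    out$circ_strength[i] <- circadianStrength(hy, npSched)
    if (!isTRUE(sub$hasEeg[i])) {
      out$excluded[i] <- TRUE
      out$reason[i] <- "no sleep-EEG data"
      next
    }
    bl <- simulateSleepEeg(p, "baseline", eegCoeffs,
                           childSeed(cohort@seed,
                                     paste0("eeg-b-", sub$subjectId[i])))
    rc <- simulateSleepEeg(p, "recovery", eegCoeffs,
                           childSeed(cohort@seed,
                                     paste0("eeg-r-", sub$subjectId[i])))
    out$delta_rebound[i] <- deltaRebound(nremDeltaPower(bl),
                                         nremDeltaPower(rc))
  }
  has <- !is.na(out$delta_rebound)
  if (sum(has) >= 5L) {
    low <- flagLowOutliers(out$delta_rebound[has])
    idx <- which(has)[low]
    out$excluded[idx] <- TRUE
    out$reason[idx] <- "delta rebound > 2 IQR below 25th percentile"
    out$delta_rebound[idx] <- NA_real_
  }
  out
}
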