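#' Generator configuration
#'
#' Resolved configuration of the synthetic-cohort generator: subject
#' heterogeneity of the two-process model, RT-model coefficients, nap
#' architecture, sleep-EEG coefficients (including the planted
#' delta-rebound distribution, the number of subjects with usable EEG
#' and the single gross outlier), and the toy-brain geometry with
#' planted BOLD effects. All values are study-condition defaults;
#' overrides are merged recursively.
#'
#' @param ... named overrides, e.g. \code{eeg = list(nEeg = 10)}.
#' @return Nested configuration list.
#' @export
cohortConfig <- function(...) {
  cfg <- list(
    kss = list(sigmaRating = 0.6, sigmaSubject = 0.35, circAmpSd = 0.12,
               phaseSd = 0.75, S0Sd = 0.04),
    pvt = c(defaultRtCoeffs(), list(lapseASd = 0.28)),
    nap = defaultNapCoeffs(),
    eeg = c(defaultEegCoeffs(),
            list(nEeg = 26L, reboundMean = 120, reboundSd = 45,
                 baselineMean = 450, baselineSd = 80,
                 outlierRebound = -350)),
    brain = list(dim = c(20L, 24L, 20L), voxelMm = 3),
    bold = defaultBoldCoeffs()
  )
  mergeConfig(cfg, list(...))
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Simulate a complete in-silico cohort
#'
#' Generates per-subject two-process parameters, KSS ratings around
#' every scan session of both protocol arms, 10-min PVT event streams
#' for every session, pre/post-nap ratings and hypnograms for the nap
#' protocol, and planted ground truth for the sleep-EEG and BOLD
#' stages. Rerunning with the same seed and configuration is
#' bit-identical. BOLD series and EEG spectra are materialised on
#' demand (\code{\link{simulateBold}}, \code{\link{simulateSleepEeg}})
#' from seeds derived from the cohort seed.
#'
#' @param nSubjects number of subjects (>= 3; default the canonical 31).
#' @param config see \code{\link{cohortConfig}}.
#' @param seed integer master seed.
#' @return A \linkS4class{Cohort}.
#' @examples
#' coh <- simulateCohort(4, seed = 1)
#' sleepinessProfile(coh, "SD")
#' @export
simulateCohort <- function(nSubjects = 31L, config = cohortConfig(),
                           seed = 1L) {
  nSubjects <- as.integer(nSubjects)
  if (nSubjects < 3L)
    stop("group inference is undefined for fewer than 3 subjects")
  seed <- as.integer(seed)
  schedules <- list(SD = protocolSchedule("SD"),
                    NP = protocolSchedule("NP"))
  base <- defaultSubjectParams()
  kc <- config$kss
  subjects <- withSeed(childSeed(seed, "params"), {
    data.frame(
      subjectId = seq_len(nSubjects),
      S0 = pmin(0.5, pmax(0.02, base$S0 + stats::rnorm(nSubjects, 0, kc$S0Sd))),
      tauRise = base$tauRise, tauDecay = base$tauDecay,
      circAmp = pmax(0.2, 1 + stats::rnorm(nSubjects, 0, kc$circAmpSd)),
      circPhase = base$circPhase + stats::rnorm(nSubjects, 0, kc$phaseSd),
      k0 = base$k0 + stats::rnorm(nSubjects, 0, kc$sigmaSubject),
      kS = base$kS, kC = base$kC, kSC = base$kSC,
      lapseAOffset = stats::rnorm(nSubjects, 0, config$pvt$lapseASd),
      boldGain = 1 + stats::rnorm(nSubjects, 0, config$bold$subjectGainSd),
      circStrengthTrue = stats::rnorm(nSubjects),
      deltaBaselineTrue = pmax(150, stats::rnorm(nSubjects,
        config$eeg$baselineMean, config$eeg$baselineSd)),
      deltaReboundTrue = stats::rnorm(nSubjects, config$eeg$reboundMean,
                                      config$eeg$reboundSd),
      hasEeg = seq_len(nSubjects) <= config$eeg$nEeg)
  })
  # one gross negative rebound outlier among the EEG subjects
  if (any(subjects$hasEeg)) {
    out <- withSeed(childSeed(seed, "outlier"),
                    sample(which(subjects$hasEeg), 1L))
    subjects$deltaReboundTrue[out] <- config$eeg$outlierRebound
  }

  kssRows <- list(); pvtRows <- list(); napRows <- list()
  hyp <- array(NA_integer_, c(nSubjects, 10L, config$nap$epochsPerNap))
  for (i in seq_len(nSubjects)) {
    p <- as.list(subjects[i, ])
    rt <- config$pvt
    rt$lapseA <- rt$lapseA + p$lapseAOffset
    for (cond in c("SD", "NP")) {
      sched <- schedules[[cond]]
      ks <- twoProcessKss(p, sched, kc$sigmaRating,
                          childSeed(seed, paste0("kss-", i, "-", cond)))
      kssRows[[length(kssRows) + 1L]] <-
        cbind(subject = i, condition = cond, ks)
      for (ses in 1:5) {
        tr <- simulatePvtSession(ks$latent[ses], rt,
          childSeed(seed, paste0("pvt-", i, "-", cond, "-", ses)))
        pvtRows[[length(pvtRows) + 1L]] <-
          cbind(subject = i, condition = cond, session = ses, tr)
      }
    }
    np <- schedules$NP
    hyp[i, , ] <- simulateHypnograms(p, np, config$nap,
                                     childSeed(seed, paste0("hyp-", i)))
    mid <- pmin(rowMeans(napWindows(np)), 40)
    latNap <- latentSleepiness(p, np, mid)
    napRows[[i]] <- withSeed(childSeed(seed, paste0("napkss-", i)), {
      data.frame(subject = i, nap = seq_along(mid), time_h = mid,
        pre = roundKss(latNap + stats::rnorm(length(mid), 0, kc$sigmaRating)),
        post = roundKss(latNap + stats::rnorm(length(mid), 0, kc$sigmaRating)))
    })
  }
  new("Cohort", subjects = subjects, schedules = schedules,
      kss = do.call(rbind, kssRows), pvt = do.call(rbind, pvtRows),
      napKss = do.call(rbind, napRows), hypnograms = hyp,
      config = config, seed = seed)
}

#' @rdname accessors
#' @export
setMethod("subjects", "Cohort", function(object) object@subjects)

#' @rdname accessors
#' @export
setMethod("nSubjects", "Cohort", function(object) nrow(object@subjects))

#' @rdname accessors
#' @export
setMethod("schedule", "Cohort",
          function(object, condition) object@schedules[[condition]])

#' @rdname accessors
#' @export
setMethod("kssRatings", "Cohort", function(object) object@kss)

#' @rdname accessors
#' @export
setMethod("pvtTrials", "Cohort", function(object) object@pvt)

#' @rdname accessors
#' @export
setMethod("napRatings", "Cohort", function(object) object@napKss)

#' @rdname accessors
#' @export
setMethod("hypnograms", "Cohort", function(object) object@hypnograms)

# Hypnogram matrix (nap x epoch) of one subject.
cohortHypnogram <- function(cohort, subject) {
  H <- cohort@hypnograms[match(subject, cohort@subjects$subjectId), , ]
  attr(H, "stages") <- stageLevels
  H
}

setMethod("show", "Cohort", function(object) {
  cat("Cohort of", nSubjects(object), "subjects (seed",
      object@seed, ")\n")
  cat("  KSS ratings:", nrow(object@kss), "session records;",
      nrow(object@napKss), "nap records\n")
  cat("  PVT trials:", nrow(object@pvt), "\n")
  cat("  EEG subjects:", sum(object@subjects$hasEeg), "\n")
})
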