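#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("arrayOrNULL", c("array", "NULL"))

#' ProtocolSchedule: timing of one 40-h constant-routine protocol arm
#'
#' Describes the scheduled sleep-wake structure of one protocol arm:
#' either 40 h of continuous wakefulness (\code{"SD"}) or 10 alternating
#' cycles of 160 min scheduled wakefulness and 80 min nap opportunities
#' (\code{"NP"}). All times are in hours elapsed since scheduled wake-up.
#'
#' @slot condition \code{"SD"} or \code{"NP"}.
#' @slot wakeTime habitual wake-up clock time in decimal hours (only used
#'   to translate elapsed time into clock time for display).
#' @slot sessionTimes elapsed hours of the five in-scanner sessions.
#' @slot napWindows two-column matrix of nap (start, end) elapsed hours;
#'   zero rows for SD.
#' @slot nightWindow (start, end) elapsed hours of the biological night.
#' @exportClass ProtocolSchedule
setClass("ProtocolSchedule",
  representation(condition = "character", wakeTime = "numeric",
                 sessionTimes = "numeric", napWindows = "matrix",
                 nightWindow = "numeric"))

setValidity("ProtocolSchedule", function(object) {
  msg <- character()
  if (!object@condition %in% c("SD", "NP"))
    msg <- c(msg, "condition must be 'SD' or 'NP'")
  if (!identical(object@sessionTimes, c(5, 13, 21, 29, 37)))
    msg <- c(msg, "sessionTimes must be 5, 13, 21, 29, 37 h")
  nw <- object@napWindows
  if (object@condition == "SD" && nrow(nw) != 0L)
    msg <- c(msg, "SD schedule must have no nap windows")
  if (object@condition == "NP") {
    if (nrow(nw) != 10L)
      msg <- c(msg, "NP schedule must have exactly 10 nap windows")
    else {
      len <- nw[, 2L] - nw[, 1L]
      gap <- nw[-1L, 1L] - nw[-10L, 2L]
      if (any(abs(len - 80 / 60) > 1e-9))
        msg <- c(msg, "each nap must last 80 min")
      if (any(abs(gap - 160 / 60) > 1e-9))
        msg <- c(msg, "naps must be separated by 160 min of wakefulness")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Cohort: a complete in-silico study
#'
#' Holds per-subject physiological parameters (including planted ground
#' truth), both protocol schedules, and all behavioural records: KSS
#' ratings around each scan session, PVT trial tables, nap-adjacent KSS
#' ratings and nap hypnograms. Voxel-level BOLD series and sleep-EEG
#' spectra are materialised on demand from per-record seeds stored in
#' the object (see \code{\link{simulateBold}} and
#' \code{\link{simulateSleepEeg}}); re-materialisation is bit-identical.
#'
#' @slot subjects data.frame of per-subject parameters and planted truth.
#' @slot schedules named list with ProtocolSchedule objects "SD" and "NP".
#' @slot kss per-session pre/post-scan ratings, long format.
#' @slot pvt PVT trial table (all subjects/conditions/sessions).
#' @slot napKss pre/post-nap ratings for each NP nap.
#' @slot hypnograms integer array subject x nap x epoch (stage codes,
#'   see \code{stageLevels}).
#' @slot config resolved generator configuration.
#' @slot seed master seed the cohort was generated from.
#' @exportClass Cohort
setClass("Cohort",
  representation(subjects = "data.frame", schedules = "list",
                 kss = "data.frame", pvt = "data.frame",
                 napKss = "data.frame", hypnograms = "array",
                 config = "list", seed = "integer"))

setValidity("Cohort", function(object) {
  msg <- character()
  if (nrow(object@subjects) < 3L)
    msg <- c(msg, "a cohort needs at least 3 subjects")
  r <- c(object@kss$pre, object@kss$post)
  if (any(!is.na(r) & (r < 1 | r > 9)))
    msg <- c(msg, "KSS ratings must lie in [1, 9]")
  if (!all(c("SD", "NP") %in% names(object@schedules)))
    msg <- c(msg, "schedules must contain both SD and NP")
  if (length(msg)) msg else TRUE
})

#' SleepinessProfile: group-mean sleepiness time course and its z-weights
#'
#' @slot condition protocol arm the profile was computed from.
#' @slot meanKss group-mean session KSS (KSS units), length 5 with NA for
#'   missing sessions.
#' @slot zWeights population z-scores of \code{meanKss} over available
#'   sessions (mean 0, population SD 1).
#' @slot nSubjects number of subjects entering each session mean.
#' @exportClass SleepinessProfile
setClass("SleepinessProfile",
  representation(condition = "character", meanKss = "numeric",
                 zWeights = "numeric", nSubjects = "integer"))

setValidity("SleepinessProfile", function(object) {
  msg <- character()
  if (length(object@meanKss) != 5L || length(object@zWeights) != 5L)
    msg <- c(msg, "meanKss and zWeights must have length 5")
  z <- object@zWeights[!is.na(object@zWeights)]
  if (length(z) >= 2L) {
    if (abs(mean(z)) > 1e-10)
      msg <- c(msg, "zWeights must have mean 0")
    if (abs(sqrt(mean((z - mean(z))^2)) - 1) > 1e-10)
      msg <- c(msg, "zWeights must have population SD 1")
  }
  if (length(msg)) msg else TRUE
})

#' ContrastSpec: a sleepiness-anchored across-session contrast
#'
#' @slot name one of \code{CxS_SD}, \code{C_on_SD}, \code{C_on_NP},
#'   \code{S_minus_C_SD}.
#' @slot condition protocol arm whose session maps the weights apply to.
#' @slot weights 5-vector of session weights, sum zero.
#' @slot direction \code{"T+"} (activation follows the profile) or
#'   \code{"T-"} (negated weights).
#' @slot speed RT range the contrast targets (\code{"fast"} or
#'   \code{"slow"}).
#' @slot degenerate flag set when the weight vector is numerically zero.
#' @exportClass ContrastSpec
setClass("ContrastSpec",
  representation(name = "character", condition = "character",
                 weights = "numeric", direction = "character",
                 speed = "character", degenerate = "logical"))

setValidity("ContrastSpec", function(object) {
  msg <- character()
  if (!object@name %in% c("CxS_SD", "C_on_SD", "C_on_NP", "S_minus_C_SD"))
    msg <- c(msg, "unknown contrast name")
  if (!object@direction %in% c("T+", "T-"))
    msg <- c(msg, "direction must be 'T+' or 'T-'")
  w <- object@weights[!is.na(object@weights)]
  if (abs(sum(w)) > 1e-10)
    msg <- c(msg, "weights must sum to zero")
  if (length(msg)) msg else TRUE
})

#' ToyBrain: a labelled desk-scale brain geometry
#'
#' A small voxel grid with an MNI-like affine (RAS, millimetre
#' coordinates centred mid-volume) and an integer atlas labelling
#' axis-aligned block regions.
#'
#' @slot dim integer grid dimensions (x, y, z).
#' @slot voxelMm isotropic voxel size in mm.
#' @slot affine 4x4 voxel-to-mm matrix (0-based voxel indices).
#' @slot atlas integer label array of dimension \code{dim}.
#' @slot labels named integer vector mapping region names to labels.
#' @exportClass ToyBrain
setClass("ToyBrain",
  representation(dim = "integer", voxelMm = "numeric", affine = "matrix",
                 atlas = "array", labels = "integer"))

setValidity("ToyBrain", function(object) {
  msg <- character()
  if (!identical(dim(object@atlas), as.integer(object@dim)))
    msg <- c(msg, "atlas shape must equal grid dimensions")
  if (length(msg)) msg else TRUE
})

#' FirstLevelResult: per-session event-related GLM fit
#'
#' @slot betas regressor x voxel matrix of OLS estimates.
#' @slot regressors column labels of the fitted design.
#' @slot sigma2 voxelwise residual variance (correct degrees of freedom).
#' @slot df residual degrees of freedom.
#' @slot brain the ToyBrain geometry the fit refers to.
#' @exportClass FirstLevelResult
setClass("FirstLevelResult",
  representation(betas = "matrix", regressors = "character",
                 sigma2 = "numeric", df = "integer", brain = "ToyBrain"))

#' StatMap: a voxelwise group-level statistic with permutation FWE p-values
#'
#' @slot t statistic array (3D).
#' @slot df degrees of freedom.
#' @slot pFwe family-wise-error corrected p-value array, or NULL before
#'   \code{\link{permutationFwe}} has been applied.
#' @slot mask logical array of analysed voxels.
#' @slot brain the ToyBrain geometry.
#' @slot provenance list describing how the map was built (contrast name,
#'   speed range, number of subjects, permutations).
#' @exportClass StatMap
setClass("StatMap",
  representation(t = "array", df = "numeric", pFwe = "arrayOrNULL",
                 mask = "array", brain = "ToyBrain", provenance = "list"))

setValidity("StatMap", function(object) {
  msg <- character()
  if (!is.null(object@pFwe)) {
    p <- object@pFwe[object@mask & !is.na(object@pFwe)]
    if (length(p) && (any(p <= 0) || any(p > 1)))
      msg <- c(msg, "FWE p-values must lie in (0, 1]")
  }
  tin <- object@t[object@mask]
  if (any(!is.finite(tin) & !is.na(tin)))
    msg <- c(msg, "t must be finite (or NA) inside the mask")
  if (length(msg)) msg else TRUE
})
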