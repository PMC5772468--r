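#' Build the four sleepiness-anchored contrast specifications
#'
#' From the SD and NP group sleepiness profiles, constructs the four
#' across-session contrasts (each as a T+/T- pair per speed range):
#' \describe{
#'   \item{CxS_SD}{z-scored SD profile applied to SD sessions — BOLD
#'     follows the circadian-by-homeostatic sleepiness interaction.}
#'   \item{C_on_SD}{z-scored NP (circadian) profile applied to SD
#'     sessions.}
#'   \item{C_on_NP}{z-scored NP profile applied to NP sessions.}
#'   \item{S_minus_C_SD}{z(SD) - z(NP) applied to SD sessions,
#'     re-centred to sum zero — the near-linear homeostatic slope
#'     after removing the circadian shape. The default sign rises with
#'     time awake; \code{flipSminusC} switches it.}
#' }
#'
#' @param sdProfile,npProfile \linkS4class{SleepinessProfile} objects.
#' @param speed speed range the contrasts target.
#' @param flipSminusC reverse the sign convention of the difference
#'   contrast.
#' @return Named list of \linkS4class{ContrastSpec} pairs
#'   (\code{$Tplus}, \code{$Tminus} each).
#' @export
makeContrastSpecs <- function(sdProfile, npProfile, speed = "fast",
                              flipSminusC = FALSE) {
  stopifnot(is(sdProfile, "SleepinessProfile"),
            is(npProfile, "SleepinessProfile"))
  zsd <- sdProfile@zWeights
  znp <- npProfile@zWeights
  if (anyNA(zsd) || anyNA(znp))
    stop("profiles have missing sessions; apply missingSessionCheck ",
         "and re-z-score before building contrasts")
  d <- zsd - znp
  d <- d - mean(d)
  if (flipSminusC) d <- -d
  degenerate <- sqrt(mean(d^2)) < 1e-8
  if (degenerate)
    warning("SD and NP profiles coincide; S_minus_C_SD is degenerate")
  pair <- function(name, condition, w, degen = FALSE) {
    list(Tplus = new("ContrastSpec", name = name, condition = condition,
                     weights = w, direction = "T+", speed = speed,
                     degenerate = degen),
         Tminus = new("ContrastSpec", name = name, condition = condition,
                      weights = -w, direction = "T-", speed = speed,
                      degenerate = degen))
  }
  list(CxS_SD = pair("CxS_SD", "SD", zsd),
       C_on_SD = pair("C_on_SD", "SD", znp),
       C_on_NP = pair("C_on_NP", "NP", znp),
       S_minus_C_SD = pair("S_minus_C_SD", "SD", d, degenerate))
}

#' @rdname accessors
#' @export
setMethod("contrastWeights", "ContrastSpec", function(object) object@weights)

#' @rdname accessors
#' @export
setMethod("condition", "ContrastSpec", function(object) object@condition)

setMethod("show", "ContrastSpec", function(object) {
  cat("ContrastSpec", object@name, object@direction,
      "(", object@condition, ",", object@speed, "RTs )\n")
  cat("  weights:", paste(format(object@weights, digits = 3),
                          collapse = ", "), "\n")
  if (object@degenerate) cat("  [degenerate: zero weights]\n")
})

#' Apply an anchored contrast to session maps
#'
#' Voxelwise weighted sum of the five session contrast volumes with the
#' specification's weights. With four available sessions (validated
#' missingness) the weights are re-standardised over the available
#' sessions rather than imputing the missing map.
#'
#' @param sessionMaps list of 5 session contrast arrays (NULL for a
#'   validated missing session).
#' @param spec a \linkS4class{ContrastSpec}.
#' @return Subject-level contrast array.
#' @export
applyAnchoredContrast <- function(sessionMaps, spec) {
  stopifnot(is(spec, "ContrastSpec"), length(sessionMaps) == 5L)
  have <- !vapply(sessionMaps, is.null, logical(1))
  if (sum(have) < 4L)
    stop("need at least 4 session maps (5 preferred)")
  dims <- lapply(sessionMaps[have], dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1L]])))
    stop("session map geometries do not match")
  w <- spec@weights
  if (!all(have)) {
    w <- w[have]
    w <- w - mean(w)
    s <- sqrt(mean(w^2))
    if (s > 1e-12) w <- w / s * sqrt(mean(spec@weights^2))
  }
  out <- array(0, dims[[1L]])
  idx <- which(have)
  for (k in seq_along(idx)) out <- out + w[k] * sessionMaps[[idx[k]]]
  out
}
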