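#' Canonical double-gamma hemodynamic response function
#'
#' Samples the canonical HRF: a gamma density peaking around 5-6 s
#' minus an undershoot gamma (delays 6 and 16, unit dispersions,
#' undershoot ratio 1/6), over 32 s, normalised to unit peak.
#'
#' @param dt sampling interval in seconds (0 < dt <= TR).
#' @param length HRF support in seconds.
#' @return Numeric vector of kernel samples at \code{seq(0, length, dt)}.
#' @examples
#' h <- canonicalHrf(0.1)
#' seq(0, 32, 0.1)[which.max(h)]  # peak near 5 s
#' @export
canonicalHrf <- function(dt, length = 32) {
  stopifnot(dt > 0)
  t <- seq(0, length, by = dt)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

# Event regressor: onset stick train on a microtime grid convolved with
# the canonical HRF, sampled at scan acquisition times. Optional stick
# heights give parametric modulation.
eventRegressor <- function(onsets, nScans, tr, heights = NULL, dt = 0.1) {
  if (is.null(heights)) heights <- rep(1, length(onsets))
  tEnd <- nScans * tr
  n <- ceiling(tEnd / dt) + 1L
  train <- numeric(n)
  keep <- onsets < tEnd
  idx <- pmin(n, floor(onsets[keep] / dt) + 1L)
  for (k in seq_along(idx))
    train[idx[k]] <- train[idx[k]] + heights[keep][k]
  h <- canonicalHrf(dt)
  conv <- stats::convolve(train, rev(h), type = "open")[seq_len(n)]
  scanIdx <- floor((0:(nScans - 1L)) * tr / dt) + 1L
  conv[scanIdx]
}
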