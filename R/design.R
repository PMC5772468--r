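#' Build the event-related first-level design matrix
#'
#' One main regressor per speed range (fast, intermediate, slow, lapse)
#' present in the session: the onset train of the range's clock events
#' convolved with the canonical HRF at scan times. Each main regressor
#' is paired with a first-order time-modulation regressor (the same
#' train weighted by the mean-centred trial index) to absorb
#' time-on-task effects. Six motion parameters, a discrete-cosine
#' high-pass drift set (128-s cutoff) and an intercept complete the
#' matrix. Event types without trials are dropped with a message; null
#' events contribute no predicted signal.
#'
#' @param pvt PVT trial table of one session (columns \code{onset_s},
#'   \code{trial_type}, \code{response_time_ms}).
#' @param partition output of \code{\link{partitionRts}} on the
#'   session's clock RTs.
#' @param motion scans x 6 matrix of motion parameters (zeros allowed).
#' @param tr repetition time (s).
#' @param nScans number of acquired volumes.
#' @param highpass drift cutoff in seconds.
#' @return List with \code{matrix} (scans x regressors, labelled),
#'   \code{tr}, \code{frameTimes} and \code{dropped} (absent event
#'   types).
#' @export
buildDesign <- function(pvt, partition, motion = NULL, tr = 2.2,
                        nScans = ceiling(600 / tr), highpass = 128) {
  clock <- pvt[pvt$trial_type == "clock", ]
  if (any(clock$onset_s > nScans * tr)) {
    warning("dropping events after the last scan")
    keep <- clock$onset_s <= nScans * tr
    clock <- clock[keep, ]
  }
  stopifnot(nrow(clock) == length(partition$labels))
  if (is.null(motion)) motion <- matrix(0, nScans, 6L)
  stopifnot(nrow(motion) == nScans, ncol(motion) == 6L)

  types <- c("fast", "intermediate", "slow", "lapse")
  cols <- list(); labels <- character(); dropped <- character()
  for (ty in types) {
    sel <- partition$labels == ty
    if (!any(sel)) {
      dropped <- c(dropped, ty)
      message("event type '", ty, "' absent; regressors dropped")
      next
    }
    onsets <- clock$onset_s[sel]
    idx <- which(sel)
    cols[[length(cols) + 1L]] <- eventRegressor(onsets, nScans, tr)
    labels <- c(labels, ty)
    tmod <- eventRegressor(onsets, nScans, tr, heights = idx - mean(idx))
    if (max(abs(tmod)) > 1e-12) {
      # a single-trial type has a degenerate (all-zero) modulation column
      cols[[length(cols) + 1L]] <- tmod
      labels <- c(labels, paste0(ty, "_tmod"))
    } else {
      message("time-modulation column for '", ty,
              "' is degenerate (single trial); dropped")
    }
  }
  for (j in 1:6) {
    m <- motion[, j]
    if (stats::sd(m) > 0) m <- (m - mean(m)) / stats::sd(m)
    cols[[length(cols) + 1L]] <- m
    labels <- c(labels, paste0("motion", j))
  }
  tEnd <- nScans * tr
  K <- floor(2 * tEnd / highpass)
  n <- nScans
  for (k in seq_len(K)) {
    cols[[length(cols) + 1L]] <- cos(pi * k * (2 * (0:(n - 1L)) + 1) / (2 * n))
    labels <- c(labels, paste0("dct", k))
  }
  cols[[length(cols) + 1L]] <- rep(1, nScans)
  labels <- c(labels, "intercept")
  X <- do.call(cbind, cols)
  colnames(X) <- labels
  list(matrix = X, tr = tr, frameTimes = (0:(nScans - 1L)) * tr,
       dropped = dropped)
}
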