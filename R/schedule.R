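#' Build a protocol schedule
#'
#' Constructs the scheduled timing of one 40-h protocol arm. Under
#' sleep deprivation (\code{"SD"}) participants stay awake for 40 h;
#' under the nap protocol (\code{"NP"}) they complete 10 alternating
#' cycles of 160 min scheduled wakefulness and 80 min nap opportunities.
#' In both arms, scan sessions take place 5, 13, 21, 29 and 37 h after
#' habitual wake-up, and the biological night spans elapsed hours 16-24.
#'
#' @param condition \code{"SD"} or \code{"NP"}.
#' @param wakeTime habitual wake-up clock time in decimal hours
#'   (default 7.2, i.e. 07:12).
#' @return A \linkS4class{ProtocolSchedule}.
#' @examples
#' protocolSchedule("NP")
#' @export
protocolSchedule <- function(condition = c("SD", "NP"), wakeTime = 7.2) {
  condition <- match.arg(condition)
  naps <- if (condition == "NP") {
    start <- (160 / 60) + (0:9) * (240 / 60)
    cbind(start = start, end = start + 80 / 60)
  } else {
    matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("start", "end")))
  }
  new("ProtocolSchedule", condition = condition, wakeTime = wakeTime,
      sessionTimes = c(5, 13, 21, 29, 37), napWindows = naps,
      nightWindow = c(16, 24))
}

#' @rdname accessors
#' @param object an object of the matching class
#' @export
setMethod("condition", "ProtocolSchedule", function(object) object@condition)

#' @rdname accessors
#' @export
setMethod("sessionTimes", "ProtocolSchedule",
          function(object) object@sessionTimes)

#' @rdname accessors
#' @export
setMethod("napWindows", "ProtocolSchedule", function(object) object@napWindows)

setMethod("show", "ProtocolSchedule", function(object) {
  cat("ProtocolSchedule (", object@condition, ")\n", sep = "")
  cat("  sessions at", paste(object@sessionTimes, collapse = ", "),
      "h elapsed\n")
  if (nrow(object@napWindows))
    cat("  ", nrow(object@napWindows), "nap windows of 80 min, first at",
        format(object@napWindows[1L, 1L], digits = 3), "h\n")
})

# Index of the nap scheduled in the evening of the first day (the one
# straddling the wake-maintenance zone, 2-3 h before habitual bedtime).
eveningNapIndex <- function(sched) {
  stopifnot(is(sched, "ProtocolSchedule"))
  if (sched@condition != "NP") stop("evening nap is defined for NP only")
  mid <- rowMeans(sched@napWindows)
  idx <- which(mid >= 13 & mid < 16.5)
  if (!length(idx)) stop("no evening nap found in schedule")
  idx[1L]
}
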