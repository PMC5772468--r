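#' Session-level sleepiness value
#'
#' The sleepiness value attached to a scan session is the arithmetic
#' mean of the ratings collected approximately 30 min before and after
#' the task. If exactly one rating is missing the other is used and the
#' value is flagged; if both are missing, NA propagates.
#'
#' @param pre,post KSS ratings in [1, 9], possibly NA.
#' @return Numeric value with attribute \code{singleRating} set to TRUE
#'   when only one rating was available.
#' @examples
#' sessionKss(5, 7)   # 6
#' sessionKss(3, NA)  # 3, flagged
#' @export
sessionKss <- function(pre, post) {
  ok <- function(x) is.na(x) | (x >= 1 & x <= 9)
  if (!ok(pre) || !ok(post)) stop("KSS ratings must lie in [1, 9]")
  if (is.na(pre) && is.na(post)) return(NA_real_)
  if (is.na(pre) || is.na(post)) {
    v <- if (is.na(pre)) post else pre
    attr(v, "singleRating") <- TRUE
    return(v)
  }
  (pre + post) / 2
}

#' Population z-scores of a session profile
#'
#' Standardises a group-mean sleepiness profile to mean 0 and
#' population SD 1 (dividing by the root mean squared deviation, not
#' the n-1 sample SD), preserving order. These are the weights used to
#' anchor session contrasts to the sleepiness time course.
#'
#' @param means numeric vector (typically length 5) with at least two
#'   distinct values.
#' @return z-scored vector of the same length.
#' @examples
#' zscoreProfile(1:5)
#' @export
zscoreProfile <- function(means) {
  if (length(means) < 2L) stop("need at least 2 values to z-score")
  zpop(means)
}

#' Partition reaction times into speed ranges
#'
#' Labels each RT as \code{lapse} (> 500 ms), else \code{fast}
#' (below the 25th percentile), \code{slow} (above the 75th percentile)
#' or \code{intermediate}. Percentiles are computed by linear
#' interpolation between order statistics over non-lapse RTs only;
#' the lapse label takes precedence.
#'
#' @param rts numeric vector of reaction times in ms (NAs are dropped);
#'   at least 8 valid RTs are required for stable percentiles.
#' @return List with \code{labels} (factor aligned with the non-NA RTs),
#'   \code{p25}, \code{p75} (ms) and the input \code{rts}.
#' @examples
#' partitionRts(c(200, 220, 240, 260, 280, 300, 320, 340))
#' @export
partitionRts <- function(rts) {
  rts <- rts[!is.na(rts)]
  if (length(rts) < 8L)
    stop("fewer than 8 valid RTs; percentiles would be unstable")
  if (any(rts <= 0)) stop("RTs must be positive")
  lapse <- rts > 500
  base <- rts[!lapse]
  if (length(base) < 8L)
    stop("fewer than 8 non-lapse RTs; percentiles would be unstable")
  p25 <- pctl(base, 0.25)
  p75 <- pctl(base, 0.75)
  lab <- ifelse(lapse, "lapse",
         ifelse(rts < p25, "fast",
         ifelse(rts > p75, "slow", "intermediate")))
  list(labels = factor(lab, levels = c("fast", "intermediate", "slow",
                                       "lapse")),
       p25 = p25, p75 = p75, rts = rts)
}

#' Group-mean sleepiness profile for one protocol arm
#'
#' Averages session KSS values (pre/post mean) over subjects and
#' z-scores the resulting 5-vector.
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param condition \code{"SD"} or \code{"NP"}.
#' @return A \linkS4class{SleepinessProfile}.
#' @export
sleepinessProfile <- function(cohort, condition = c("SD", "NP")) {
  condition <- match.arg(condition)
  k <- cohort@kss[cohort@kss$condition == condition, ]
  val <- mapply(sessionKss, k$pre, k$post)
  means <- tapply(val, k$session, mean, na.rm = TRUE)
  n <- tapply(!is.na(val), k$session, sum)
  m5 <- as.numeric(means[as.character(1:5)])
  new("SleepinessProfile", condition = condition, meanKss = m5,
      zWeights = zscoreProfile(m5), nSubjects = as.integer(n))
}

#' @rdname accessors
#' @export
setMethod("meanKss", "SleepinessProfile", function(object) object@meanKss)

#' @rdname accessors
#' @export
setMethod("zWeights", "SleepinessProfile", function(object) object@zWeights)

#' @rdname accessors
#' @export
setMethod("condition", "SleepinessProfile", function(object) object@condition)

setMethod("show", "SleepinessProfile", function(object) {
  cat("SleepinessProfile (", object@condition, ")\n", sep = "")
  cat("  mean KSS:", paste(format(object@meanKss, digits = 3),
                           collapse = ", "), "\n")
  cat("  z-weights:", paste(format(object@zWeights, digits = 3),
                            collapse = ", "), "\n")
})

#' Behavioural summary by condition and session
#'
#' Tabulates mean (and SEM) session KSS, fast/slow RT means and lapse
#' counts by condition and session, with paired sign-flip permutation
#' p-values for the SD-vs-NP difference per session.
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param nPerm permutations for the paired sign-flip test.
#' @param seed seed for the permutation draw.
#' @return data.frame, one row per condition x session cell.
#' @export
behavioralSummary <- function(cohort, nPerm = 2000L, seed = 1L) {
  if (nSubjects(cohort) < 3L) stop("need at least 3 subjects")
  subj <- cohort@subjects$subjectId
  perSubj <- function(condition) {
    k <- cohort@kss[cohort@kss$condition == condition, ]
    kssm <- tapply(mapply(sessionKss, k$pre, k$post),
                   list(k$subject, k$session), mean)
    p <- cohort@pvt[cohort@pvt$condition == condition &
                    cohort@pvt$trial_type == "clock", ]
    fast <- slow <- lapses <- fastRt <- slowRt <-
      matrix(NA_real_, length(subj), 5L, dimnames = list(subj, 1:5))
    for (s in subj) for (ses in 1:5) {
      rts <- p$response_time_ms[p$subject == s & p$session == ses]
      if (length(rts) < 8L) next
      part <- partitionRts(rts)
      tab <- table(part$labels)
      fast[as.character(s), ses] <- tab[["fast"]]
      slow[as.character(s), ses] <- tab[["slow"]]
      lapses[as.character(s), ses] <- tab[["lapse"]]
      fastRt[as.character(s), ses] <- mean(part$rts[part$labels == "fast"])
      slowRt[as.character(s), ses] <-
        mean(part$rts[part$labels == "slow" | part$labels == "lapse"])
    }
    list(kss = kssm, fast = fast, slow = slow, lapses = lapses,
         fastRt = fastRt, slowRt = slowRt)
  }
  sd_ <- perSubj("SD"); np_ <- perSubj("NP")
  signFlipP <- function(x, y) {
    d <- x - y; d <- d[!is.na(d)]
    if (!length(d)) return(NA_real_)
    obs <- abs(mean(d))
    perm <- withSeed(seed, vapply(seq_len(nPerm), function(i) {
      abs(mean(d * sample(c(-1, 1), length(d), replace = TRUE)))
    }, numeric(1)))
    (1 + sum(perm >= obs - 1e-12)) / (nPerm + 1)
  }
  rows <- list()
  for (cond in c("SD", "NP")) {
    x <- if (cond == "SD") sd_ else np_
    for (ses in 1:5) {
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, session = ses,
        kss_mean = mean(x$kss[, ses], na.rm = TRUE),
        kss_sem = stats::sd(x$kss[, ses], na.rm = TRUE) /
          sqrt(sum(!is.na(x$kss[, ses]))),
        fast_rt_mean = mean(x$fastRt[, ses], na.rm = TRUE),
        slow_rt_mean = mean(x$slowRt[, ses], na.rm = TRUE),
        fast_n_mean = mean(x$fast[, ses], na.rm = TRUE),
        slow_n_mean = mean(x$slow[, ses], na.rm = TRUE),
        lapses_mean = mean(x$lapses[, ses], na.rm = TRUE),
        lapses_sem = stats::sd(x$lapses[, ses], na.rm = TRUE) /
          sqrt(sum(!is.na(x$lapses[, ses]))),
        p_cond_kss = if (cond == "SD")
          signFlipP(sd_$kss[, ses], np_$kss[, ses]) else NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Cross-correlation inclusion check for gapped session profiles
#'
#' Decides whether a subject's session profile with missing sessions is
#' still representative of the reference group profile: TRUE when the
#' Pearson correlation over the shared sessions is significant at
#' alpha = 0.05 (one-sided, positive association).
#'
#' @param profile numeric 5-vector with NAs at missing sessions.
#' @param reference complete numeric 5-vector (group profile).
#' @param alpha significance level.
#' @return TRUE/FALSE; FALSE with a warning when fewer than 3 shared
#'   sessions are available.
#' @export
missingSessionCheck <- function(profile, reference, alpha = 0.05) {
  ok <- !is.na(profile) & !is.na(reference)
  if (sum(ok) < 3L) {
    warning("fewer than 3 shared sessions; subject not includable")
    return(FALSE)
  }
  x <- profile[ok]; y <- reference[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(FALSE)
  ct <- stats::cor.test(x, y, alternative = "greater")
  is.finite(ct$p.value) && ct$p.value < alpha ||
    isTRUE(all.equal(stats::cor(x, y), 1))
}
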