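# Flatten a list of 3D subject maps into an n x V matrix.
mapsToMatrix <- function(maps) {
  if (is.matrix(maps)) return(maps)
  stopifnot(is.list(maps), length(maps) >= 1L)
  t(vapply(maps, as.numeric, numeric(length(maps[[1L]]))))
}

#' Voxelwise one-sample t-test
#'
#' \code{t = mean / (sd / sqrt(n))} with \code{df = n - 1} at every
#' voxel; zero-variance voxels are set to NA with a message.
#'
#' @param maps list of n subject contrast arrays (n >= 3), or an
#'   n x V matrix.
#' @param brain the \linkS4class{ToyBrain} geometry.
#' @param mask optional logical array restricting the analysis.
#' @return A \linkS4class{StatMap} (no FWE p-values yet; see
#'   \code{\link{permutationFwe}}).
#' @export
oneSampleT <- function(maps, brain, mask = NULL) {
  X <- mapsToMatrix(maps)
  n <- nrow(X)
  if (n < 3L) stop("one-sample inference needs at least 3 subjects")
  if (is.null(mask)) mask <- array(TRUE, brain@dim)
  mu <- colMeans(X)
  s <- sqrt(colSums(sweep(X, 2L, mu)^2) / (n - 1L))
  t <- mu / (s / sqrt(n))
  zv <- s < .Machine$double.eps^0.75
  if (any(zv & as.logical(mask))) {
    message(sum(zv & as.logical(mask)),
            " zero-variance voxels set to NA")
  }
  t[zv] <- NA_real_
  new("StatMap", t = array(t, brain@dim), df = n - 1, pFwe = NULL,
      mask = mask, brain = brain,
      provenance = list(type = "onesample", n = n))
}

#' Voxelwise covariate-slope t-test
#'
#' Simple regression of subject contrast values on a mean-centred
#' covariate at every voxel; returns the slope t with \code{df = n - 2}.
#' Subjects with NA covariate (excluded by the marker stage) are
#' removed first. Numerically perfect fits are capped at |t| = 1e6 and
#' flagged in the provenance.
#'
#' @param maps list of subject contrast arrays or an n x V matrix.
#' @param covariate numeric vector aligned with the maps.
#' @param brain the geometry.
#' @param mask optional logical array.
#' @return A \linkS4class{StatMap}.
#' @export
covariateSlopeT <- function(maps, covariate, brain, mask = NULL) {
  X <- mapsToMatrix(maps)
  keep <- !is.na(covariate)
  X <- X[keep, , drop = FALSE]
  cv <- covariate[keep]
  n <- nrow(X)
  if (n < 4L) stop("covariate inference needs at least 4 subjects")
  if (stats::sd(cv) == 0) stop("covariate is constant")
  if (is.null(mask)) mask <- array(TRUE, brain@dim)
  st <- slopeTStat(X, cv)
  capped <- attr(st, "capped")
  new("StatMap", t = array(st, brain@dim), df = n - 2, pFwe = NULL,
      mask = mask, brain = brain,
      provenance = list(type = "slope", n = n,
                        cappedPerfectFit = capped))
}

slopeTStat <- function(X, cv) {
  n <- nrow(X)
  tc <- cv - mean(cv)
  Scc <- sum(tc^2)
  mu <- colMeans(X)
  Syy <- colSums(X^2) - n * mu^2
  num <- as.numeric(tc %*% X)
  slope <- num / Scc
  rss <- pmax(Syy - slope^2 * Scc, 0)
  se2 <- rss / (n - 2) / Scc
  t <- slope / sqrt(se2)
  capped <- !is.finite(t) | abs(t) > 1e6
  t[capped] <- sign(slope[capped]) * 1e6
  t[Syy < .Machine$double.eps^0.75] <- NA_real_
  attr(t, "capped") <- any(capped)
  t
}

#' Permutation-based family-wise-error corrected p-values (maxT)
#'
#' One-sided FWE inference by the permutation distribution of the
#' maximum statistic over the analysis mask: sign-flipping of subject
#' maps for one-sample tests, covariate permutation for slope tests.
#' \code{p(v) = (1 + #\{perm maxT >= t(v)\}) / (nPerm + 1)}. When fewer
#' than \code{nPerm} distinct sign patterns exist, the full set is
#' enumerated with a warning.
#'
#' @param maps list of subject arrays or n x V matrix.
#' @param brain the geometry.
#' @param type \code{"onesample"} or \code{"slope"}.
#' @param covariate required for slope tests.
#' @param nPerm number of permutations (>= 500).
#' @param seed integer seed for the permutation draw.
#' @param mask optional logical array (e.g. an ROI for small-volume
#'   correction).
#' @return A \linkS4class{StatMap} with the FWE p-value volume filled.
#' @export
permutationFwe <- function(maps, brain, type = c("onesample", "slope"),
                           covariate = NULL, nPerm = 1000L, seed = 1L,
                           mask = NULL) {
  type <- match.arg(type)
  if (nPerm < 500L) stop("at least 500 permutations are required")
  X <- mapsToMatrix(maps)
  if (type == "slope") {
    keep <- !is.na(covariate)
    X <- X[keep, , drop = FALSE]
    covariate <- covariate[keep]
  }
  n <- nrow(X)
  base <- if (type == "onesample") oneSampleT(X, brain, mask)
          else covariateSlopeT(X, covariate, brain, mask)
  mask <- base@mask
  inMask <- as.logical(mask)
  Xm <- X[, inMask, drop = FALSE]
  tObs <- as.numeric(base@t)[inMask]

  if (type == "onesample") {
    exhaustive <- 2^n <= nPerm
    if (exhaustive) {
      warning("fewer than nPerm distinct sign patterns; ",
              "enumerating all ", 2^n, " exhaustively")
      S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      nEff <- nrow(S) - 1L  # identity counted via the +1 convention
      S <- S[rowSums(S == 1) < n, , drop = FALSE]
    } else {
      S <- withSeed(seed, matrix(sample(c(-1, 1), nPerm * n,
                                        replace = TRUE), nPerm, n))
      nEff <- nPerm
    }
    ss <- colSums(Xm^2)
    M <- (S %*% Xm) / n
    V2 <- sweep(-n * M^2, 2L, ss, "+") / (n - 1L)
    Tm <- M / sqrt(V2 / n)
    Tm[!is.finite(Tm)] <- NA
    maxT <- apply(Tm, 1L, max, na.rm = TRUE)
  } else {
    nEff <- nPerm
    C <- withSeed(seed, t(vapply(seq_len(nPerm), function(i)
      sample(covariate), numeric(n))))
    maxT <- vapply(seq_len(nPerm), function(i)
      max(slopeTStat(Xm, C[i, ]), na.rm = TRUE), numeric(1))
  }
  cnt <- vapply(tObs, function(tv)
    if (is.na(tv)) NA_integer_ else sum(maxT >= tv - 1e-12), integer(1))
  p <- (1 + cnt) / (nEff + 1)
  pVol <- array(NA_real_, brain@dim)
  pVol[inMask] <- p
  base@pFwe <- pVol
  base@provenance <- c(base@provenance,
                       list(nPerm = nEff, seed = seed))
  validObject(base)
  base
}

#' Small-volume correction within a region of interest
#'
#' Re-runs the maxT permutation within the ROI mask only, so the
#' family of tests (and thus the corrected threshold) is restricted to
#' a-priori voxels.
#'
#' @inheritParams permutationFwe
#' @param roiMask logical array, non-empty, matching the geometry.
#' @return A \linkS4class{StatMap} restricted to the ROI.
#' @export
roiSmallVolume <- function(maps, brain, roiMask, ...) {
  if (!identical(dim(roiMask), as.integer(brain@dim)))
    stop("ROI mask geometry does not match")
  if (!any(roiMask)) stop("ROI mask is empty")
  sm <- permutationFwe(maps, brain, mask = array(as.logical(roiMask),
                                                 brain@dim), ...)
  sm@provenance$roi <- TRUE
  sm
}

#' Exclusive masking between speed ranges
#'
#' Removes from the primary map every voxel that exceeds an
#' uncorrected threshold (same-direction one-sided p < \code{pThresh})
#' in the other speed range's map, before FWE peak listing. Surviving
#' FWE-significant peaks are thereby specific to the primary speed
#' range and are flagged as such in \code{\link{peakTable}}.
#'
#' @param primary,other \linkS4class{StatMap} objects on the same
#'   geometry (the other map in the same contrast direction).
#' @param pThresh uncorrected exclusion threshold.
#' @return The primary StatMap with the exclusive mask applied.
#' @export
exclusiveMask <- function(primary, other, pThresh = 0.05) {
  if (!identical(dim(primary@t), dim(other@t)))
    stop("StatMap geometries do not match")
  pOther <- stats::pt(other@t, df = other@df, lower.tail = FALSE)
  drop <- !is.na(pOther) & pOther < pThresh
  newMask <- primary@mask & !drop
  out <- primary
  out@mask <- newMask
  if (!is.null(out@pFwe)) out@pFwe[!newMask] <- NA_real_
  out@t[!newMask] <- NA_real_
  out@provenance$exclusiveMasked <- TRUE
  out
}

#' Peak table of a thresholded statistic map
#'
#' Lists local maxima (26-neighbourhood) of the statistic among voxels
#' with FWE p <= \code{alpha}, labelled by atlas region and hemisphere
#' (sign of the x mm coordinate; \code{B} at x = 0), with mm
#' coordinates from the affine and the standard-normal (Z) equivalent
#' of the t value. Rows are sorted by FWE p, ties broken by
#' descending |t|.
#'
#' @param statmap a \linkS4class{StatMap} with FWE p-values.
#' @param alpha significance threshold.
#' @return data.frame with columns region, side, z, p_fwe, x, y, z_mm,
#'   t, speed_specific (possibly empty).
#' @export
peakTable <- function(statmap, alpha = 0.05) {
  if (is.null(statmap@pFwe))
    stop("statmap has no FWE p-values; run permutationFwe first")
  brain <- statmap@brain
  d <- brain@dim
  sig <- which(!is.na(statmap@pFwe) & statmap@pFwe <= alpha &
               statmap@mask, arr.ind = TRUE)
  rows <- list()
  if (nrow(sig)) {
    tv <- statmap@t
    for (r in seq_len(nrow(sig))) {
      i <- sig[r, 1L]; j <- sig[r, 2L]; k <- sig[r, 3L]
      t0 <- tv[i, j, k]
      nb <- expand.grid(i + (-1:1), j + (-1:1), k + (-1:1))
      nb <- nb[!(nb[, 1] == i & nb[, 2] == j & nb[, 3] == k), ]
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 &
        nb[, 2] <= d[2] & nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- as.matrix(nb[ok, ])
      tn <- tv[nb]
      if (any(!is.na(tn) & tn > t0)) next
      mm <- voxelToMm(brain, c(i, j, k) - 1)
      lab <- brain@atlas[i, j, k]
      region <- if (lab == 0L) "background"
                else names(brain@labels)[match(lab, brain@labels)]
      side <- if (mm[1] > 0) "R" else if (mm[1] < 0) "L" else "B"
      rows[[length(rows) + 1L]] <- data.frame(
        region = region, side = side,
        z = tToZ(t0, statmap@df),
        p_fwe = statmap@pFwe[i, j, k],
        x = mm[1], y = mm[2], z_mm = mm[3], t = t0,
        speed_specific = isTRUE(statmap@provenance$exclusiveMasked))
    }
  }
  if (!length(rows)) {
    return(data.frame(region = character(), side = character(),
                      z = numeric(), p_fwe = numeric(), x = numeric(),
                      y = numeric(), z_mm = numeric(), t = numeric(),
                      speed_specific = logical()))
  }
  out <- do.call(rbind, rows)
  out[order(out$p_fwe, -abs(out$t)), , drop = FALSE]
}

# Standard-normal quantile matching the t tail probability (stable for
# large t via log probabilities).
tToZ <- function(t, df) {
  lp <- stats::pt(t, df, lower.tail = FALSE, log.p = TRUE)
  -stats::qnorm(lp, log.p = TRUE)
}

#' @rdname accessors
#' @export
setMethod("tVolume", "StatMap", function(object) object@t)

#' @rdname accessors
#' @export
setMethod("fweVolume", "StatMap", function(object) object@pFwe)

setMethod("show", "StatMap", function(object) {
  pv <- object@provenance
  cat("StatMap (", pv$type, ", n =", pv$n, ", df =", object@df, ")\n")
  if (!is.null(object@pFwe)) {
    nsig <- sum(object@pFwe <= 0.05 & object@mask, na.rm = TRUE)
    cat("  ", nsig, "voxels with FWE p <= 0.05 (",
        pv$nPerm, "permutations )\n")
  } else cat("  no FWE p-values yet\n")
})
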