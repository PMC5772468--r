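#' Fit the first-level GLM by ordinary least squares
#'
#' Voxelwise OLS estimation of the event-related design. The
#' generator's AR(1) noise leaves OLS unbiased (group inference is
#' permutation-based, so first-level efficiency is not critical); this
#' is a deliberate design choice over prewhitening.
#'
#' @param bold BOLD session as returned by \code{\link{simulateBold}}
#'   (fields \code{data}: scans x voxels, \code{brain}).
#' @param design output of \code{\link{buildDesign}}.
#' @return A \linkS4class{FirstLevelResult}.
#' @export
fitGlm <- function(bold, design) {
  X <- design$matrix
  Y <- bold$data
  stopifnot(nrow(Y) == nrow(X))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  betas <- qr.coef(qrX, Y)
  res <- Y - X %*% betas
  df <- nrow(X) - qrX$rank
  sigma2 <- colSums(res^2) / df
  rownames(betas) <- colnames(X)
  new("FirstLevelResult", betas = betas, regressors = colnames(X),
      sigma2 = as.numeric(sigma2), df = as.integer(df),
      brain = bold$brain)
}

#' @rdname accessors
#' @param regressor regressor label, e.g. \code{"fast"}
#' @export
setMethod("betaVolume", "FirstLevelResult", function(object, regressor) {
  if (!regressor %in% object@regressors)
    stop("regressor '", regressor, "' not present in the fitted design")
  array(object@betas[regressor, ], object@brain@dim)
})

setMethod("show", "FirstLevelResult", function(object) {
  cat("FirstLevelResult:", length(object@regressors), "regressors x",
      ncol(object@betas), "voxels, df =", object@df, "\n")
})

#' Session contrast volume for one speed range
#'
#' Returns the main-effect beta volume of the requested speed
#' regressor, i.e. the session's response amplitude for that RT range.
#'
#' @param fit a \linkS4class{FirstLevelResult}.
#' @param speed \code{"fast"} or \code{"slow"} (any fitted event
#'   regressor is accepted).
#' @return 3D array of contrast values.
#' @export
sessionContrast <- function(fit, speed = c("fast", "slow")) {
  speed <- match.arg(speed, choices = c("fast", "slow", "intermediate",
                                        "lapse"))
  betaVolume(fit, speed)
}

#' Gaussian spatial smoothing
#'
#' Separable isotropic Gaussian smoothing with
#' \code{sigma = fwhm / (2 sqrt(2 log 2))} per axis in mm, converted to
#' voxels via the voxel size. Edges are renormalised (kernel mass
#' restricted to the volume), so constant images are preserved.
#'
#' @param volume 3D array.
#' @param fwhmMm full width at half maximum in mm (0 = identity).
#' @param voxelMm isotropic voxel size in mm.
#' @return Smoothed array of the same dimension.
#' @export
smoothVolume <- function(volume, fwhmMm, voxelMm = 3) {
  stopifnot(fwhmMm >= 0)
  if (fwhmMm == 0) return(volume)
  sigma <- fwhmMm / (2 * sqrt(2 * log(2))) / voxelMm
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  num <- convSep3(volume, k)
  den <- convSep3(array(1, dim(volume)), k)
  num / den
}

# Separable zero-padded 3D convolution with a 1D kernel applied along
# each axis (shift-and-add; kernels are short).
convSep3 <- function(vol, k) {
  r <- (length(k) - 1L) / 2L
  d <- dim(vol)
  for (ax in 1:3) {
    out <- array(0, d)
    for (j in seq_along(k)) {
      s <- j - r - 1L
      idxSrc <- max(1L, 1L + s):min(d[ax], d[ax] + s)
      idxDst <- idxSrc - s
      if (ax == 1L) out[idxDst, , ] <- out[idxDst, , ] +
          k[j] * vol[idxSrc, , , drop = FALSE]
      else if (ax == 2L) out[, idxDst, ] <- out[, idxDst, ] +
          k[j] * vol[, idxSrc, , drop = FALSE]
      else out[, , idxDst] <- out[, , idxDst] +
          k[j] * vol[, , idxSrc, drop = FALSE]
    }
    vol <- out
  }
  vol
}
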