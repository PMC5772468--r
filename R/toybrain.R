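# Fractional bounding boxes (of the grid dimensions) for the atlas
# regions; axis-aligned, mutually disjoint blocks. A region may own
# several blocks (bilateral structures).
.regionBoxes <- list(
  thalamus = list(c(0.35, 0.65, 0.42, 0.62, 0.40, 0.60)),
  putamen = list(c(0.08, 0.32, 0.42, 0.65, 0.36, 0.62),
                 c(0.68, 0.92, 0.42, 0.65, 0.36, 0.62)),
  postcentral = list(c(0.25, 0.75, 0.30, 0.45, 0.75, 0.95)),
  parietal = list(c(0.25, 0.75, 0.08, 0.28, 0.62, 0.90)),
  lingual = list(c(0.30, 0.70, 0.02, 0.20, 0.15, 0.40)),
  frontal = list(c(0.25, 0.75, 0.75, 0.95, 0.45, 0.80)))

#' Construct the labelled toy brain
#'
#' A desk-scale brain: an isotropic voxel grid with an MNI-like RAS
#' affine centred mid-volume, and an integer atlas labelling six
#' axis-aligned block regions (thalamus, putamen, postcentral,
#' parietal, lingual, frontal; 0 = background). Region blocks are
#' defined as fractions of the grid so the same anatomy scales to any
#' grid size.
#'
#' @param dim integer grid dimensions (default 20 x 24 x 20).
#' @param voxelMm isotropic voxel size in mm (default 3).
#' @return A \linkS4class{ToyBrain}.
#' @examples
#' tb <- toyBrain()
#' table(atlas(tb))
#' @export
toyBrain <- function(dim = c(20L, 24L, 20L), voxelMm = 3) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 8L))
  atlas <- array(0L, dim)
  labels <- stats::setNames(seq_along(.regionBoxes), names(.regionBoxes))
  for (nm in names(.regionBoxes)) {
    for (box in .regionBoxes[[nm]]) {
      lo <- pmax(1L, ceiling(box[c(1, 3, 5)] * dim))
      hi <- pmin(dim, floor(box[c(2, 4, 6)] * dim))
      atlas[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- labels[[nm]]
    }
  }
  aff <- diag(c(voxelMm, voxelMm, voxelMm, 1))
  aff[1:3, 4] <- -(dim - 1) / 2 * voxelMm
  new("ToyBrain", dim = dim, voxelMm = voxelMm, affine = aff,
      atlas = atlas, labels = labels)
}

#' @rdname accessors
#' @export
setMethod("atlas", "ToyBrain", function(object) object@atlas)

#' @rdname accessors
#' @export
setMethod("atlasLabels", "ToyBrain", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("affine", "ToyBrain", function(object) object@affine)

setMethod("show", "ToyBrain", function(object) {
  cat("ToyBrain", paste(object@dim, collapse = " x "), "voxels at",
      object@voxelMm, "mm\n")
  for (nm in names(object@labels))
    cat(sprintf("  %-12s label %d, %d voxels\n", nm, object@labels[[nm]],
                sum(object@atlas == object@labels[[nm]])))
})

#' mm coordinates (RAS) of 0-based voxel indices
#'
#' @param brain a \linkS4class{ToyBrain}.
#' @param ijk 0-based voxel index vector or matrix (rows).
#' @return Matrix of mm coordinates.
#' @export
voxelToMm <- function(brain, ijk) {
  ijk <- rbind(ijk)
  t(brain@affine %*% t(cbind(ijk, 1)))[, 1:3, drop = FALSE]
}

#' Logical mask of one named atlas region
#'
#' @param brain a \linkS4class{ToyBrain}.
#' @param region region name (must be an atlas label).
#' @return Logical array over the grid.
#' @export
regionMask <- function(brain, region) {
  if (!region %in% names(brain@labels))
    stop("unknown region label: ", region)
  brain@atlas == brain@labels[[region]]
}
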