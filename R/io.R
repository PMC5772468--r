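#' Write a volume as NIfTI-1
#'
#' Stores a 3D array (or scans-last 4D array) as float32 NIfTI with the
#' toy brain's affine in the sform.
#'
#' @param volume numeric array.
#' @param file output path (.nii or .nii.gz).
#' @param brain a \linkS4class{ToyBrain} providing the affine.
#' @return The file path, invisibly.
#' @export
writeBrainVolume <- function(volume, file, brain) {
  img <- RNifti::asNifti(volume, datatype = "float")
  img <- RNifti::`sform<-`(img, structure(brain@affine, code = 2L))
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Read a NIfTI volume into a toy-brain dataset
#'
#' @param file NIfTI path.
#' @param brain optional \linkS4class{ToyBrain}; when given, the stored
#'   spatial dimensions and affine must match.
#' @return List with \code{data} (array) and \code{affine}.
#' @export
readBrainVolume <- function(file, brain = NULL) {
  img <- tryCatch(RNifti::readNifti(file), error = function(e)
    stop("not a readable NIfTI-1 file: ", file, " (", conditionMessage(e),
         ")", call. = FALSE))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  if (!is.null(brain)) {
    if (!identical(as.integer(dim(img)[1:3]), brain@dim))
      stop("volume dimensions do not match the expected geometry")
    if (max(abs(aff - brain@affine)) > 1e-4)
      stop("volume affine does not match the expected geometry")
  }
  list(data = array(as.numeric(img), dim(img)), affine = aff)
}

#' Write / read tab-separated tables
#'
#' Events, ratings and hypnogram tables are exchanged as plain TSV
#' with a BIDS-like column convention (onsets in seconds, response
#' times in ms).
#'
#' @param x data.frame.
#' @param file path.
#' @return The path (write) or a data.frame (read), invisibly for
#'   write.
#' @export
writeTsv <- function(x, file) {
  utils::write.table(x, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname writeTsv
#' @export
readTsv <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write and hash a run configuration
#'
#' Configurations are serialised as YAML; the MD5 of the canonical
#' YAML text is the config hash recorded in every manifest.
#'
#' @param config nested configuration list.
#' @param file output path.
#' @return The config hash string, invisibly.
#' @export
writeRunConfig <- function(config, file) {
  yaml::write_yaml(config, file)
  invisible(unname(tools::md5sum(file)))
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(file) yaml::read_yaml(file)

configHash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(config, f)
  unname(tools::md5sum(f))
}

# Manifest plumbing: each pipeline stage writes <stage>-manifest.yaml
# listing its seed, config hash and artifact checksums; downstream
# stages refuse to run without their upstream manifest.
writeManifest <- function(outDir, stage, seed, hash, files) {
  man <- list(stage = stage, seed = as.integer(seed), config_hash = hash,
              files = as.list(stats::setNames(
                unname(tools::md5sum(files)), basename(files))))
  yaml::write_yaml(man, file.path(outDir, paste0(stage, "-manifest.yaml")))
  invisible(man)
}

readManifest <- function(outDir, stage, neededBy = NULL) {
  f <- file.path(outDir, paste0(stage, "-manifest.yaml"))
  if (!file.exists(f)) {
    stop("missing artifact of stage '", stage, "'",
         if (!is.null(neededBy)) paste0(" (required by '", neededBy, "')"),
         "; run the '", stage, "' stage first", call. = FALSE)
  }
  yaml::read_yaml(f)
}

logLine <- function(seed, hash, ...) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
          " [seed ", seed, " cfg ", substr(hash, 1, 8), "] ", ...)
}
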