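#' Run the analysis pipeline
#'
#' Orchestrates the full in-silico study: cohort simulation,
#' behavioural summaries, sleep markers, first-level GLM fits,
#' sleepiness-anchored contrasts and permutation group inference, each
#' stage writing plain-text / NIfTI artifacts plus a manifest (seed,
#' config hash, artifact checksums) into \code{outDir}. Later stages
#' reconstruct their inputs deterministically from the upstream
#' manifests, so rerunning any stage reproduces its outputs
#' bit-identically.
#'
#' @param outDir output directory (created if needed).
#' @param stages character vector of stages to run, in order; subset of
#'   \code{c("simulate", "behavior", "markers", "first-level",
#'   "contrasts", "group", "report")} or \code{"all"}.
#' @param nSubjects cohort size.
#' @param seed master seed.
#' @param nPerm permutations for group inference.
#' @param config generator configuration, see \code{\link{cohortConfig}}.
#' @param alpha FWE significance level for peak tables.
#' @return Invisibly, the output directory.
#' @export
runPipeline <- function(outDir, stages = "all", nSubjects = 8L, seed = 1L,
                        nPerm = 500L, config = cohortConfig(),
                        alpha = 0.05) {
  all <- c("simulate", "behavior", "markers", "first-level", "contrasts",
           "group", "report")
  if (identical(stages, "all")) stages <- all
  stopifnot(all(stages %in% all))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  run <- list(nSubjects = as.integer(nSubjects), seed = as.integer(seed),
              nPerm = as.integer(nPerm), alpha = alpha,
              generator = config)
  hash <- configHash(run)
  for (st in stages) {
    logLine(seed, hash, "stage ", st, " starting")
    switch(st,
      "simulate" = stageSimulate(outDir, run, hash),
      "behavior" = stageBehavior(outDir, run, hash),
      "markers" = stageMarkers(outDir, run, hash),
      "first-level" = stageFirstLevel(outDir, run, hash),
      "contrasts" = stageContrasts(outDir, run, hash),
      "group" = stageGroup(outDir, run, hash),
      "report" = stageReport(outDir, run, hash))
    logLine(seed, hash, "stage ", st, " done")
  }
  invisible(outDir)
}

# Rebuild the cohort exactly as the simulate stage did, from its
# manifest-recorded run parameters.
cohortFromManifest <- function(outDir, run, neededBy) {
  man <- readManifest(outDir, "simulate", neededBy)
  simulateCohort(run$nSubjects, run$generator, run$seed)
}

stageSimulate <- function(outDir, run, hash) {
  coh <- simulateCohort(run$nSubjects, run$generator, run$seed)
  files <- file.path(outDir, c("config.yaml", "kss.tsv", "pvt_events.tsv",
                               "nap_kss.tsv", "hypnograms.tsv",
                               "subjects.tsv", "atlas.nii.gz"))
  writeRunConfig(run, files[1L])
  writeTsv(coh@kss, files[2L])
  writeTsv(coh@pvt, files[3L])
  writeTsv(coh@napKss, files[4L])
  hy <- coh@hypnograms
  hyDf <- data.frame(subject = rep(seq_len(dim(hy)[1L]), times = dim(hy)[2L]),
                     nap = rep(seq_len(dim(hy)[2L]), each = dim(hy)[1L]))
  hyDf <- cbind(hyDf, matrix(hy, nrow(hyDf), dim(hy)[3L]))
  names(hyDf)[-(1:2)] <- paste0("e", seq_len(dim(hy)[3L]))
  writeTsv(hyDf, files[5L])
  writeTsv(coh@subjects, files[6L])
  brain <- toyBrain(run$generator$brain$dim, run$generator$brain$voxelMm)
  writeBrainVolume(brain@atlas, files[7L], brain)
  writeManifest(outDir, "simulate", run$seed, hash, files)
}

stageBehavior <- function(outDir, run, hash) {
  coh <- cohortFromManifest(outDir, run, "behavior")
  files <- file.path(outDir, c("behavioral_summary.tsv",
                               "sleepiness_profiles.tsv"))
  writeTsv(behavioralSummary(coh, seed = run$seed), files[1L])
  pr <- lapply(c("SD", "NP"), function(cd) {
    p <- sleepinessProfile(coh, cd)
    data.frame(condition = cd, session = 1:5, mean_kss = p@meanKss,
               z_weight = p@zWeights, n = p@nSubjects)
  })
  writeTsv(do.call(rbind, pr), files[2L])
  writeManifest(outDir, "behavior", run$seed, hash, files)
}

stageMarkers <- function(outDir, run, hash) {
  coh <- cohortFromManifest(outDir, run, "markers")
  f <- file.path(outDir, "markers.tsv")
  writeTsv(markerTable(coh, run$generator$eeg), f)
  writeManifest(outDir, "markers", run$seed, hash, f)
}

stageFirstLevel <- function(outDir, run, hash) {
  coh <- cohortFromManifest(outDir, run, "first-level")
  brain <- toyBrain(run$generator$brain$dim, run$generator$brain$voxelMm)
  files <- character()
  for (s in coh@subjects$subjectId) for (cond in c("SD", "NP")) {
    maps <- subjectContrastMaps(coh, s, cond, c("fast", "slow"), brain)
    for (sp in c("fast", "slow")) {
      f <- file.path(outDir, sprintf("sub%02d_%s_%s_sessions.nii.gz",
                                     s, cond, sp))
      writeBrainVolume(array(unlist(maps[[sp]]), c(brain@dim, 5L)), f,
                       brain)
      files <- c(files, f)
    }
  }
  writeManifest(outDir, "first-level", run$seed, hash, files)
}

stageContrasts <- function(outDir, run, hash) {
  coh <- cohortFromManifest(outDir, run, "contrasts")
  readManifest(outDir, "first-level", "contrasts")
  brain <- toyBrain(run$generator$brain$dim, run$generator$brain$voxelMm)
  specs <- makeContrastSpecs(sleepinessProfile(coh, "SD"),
                             sleepinessProfile(coh, "NP"))
  files <- character()
  for (sp in c("fast", "slow")) for (nm in names(specs)) {
    vols <- lapply(coh@subjects$subjectId, function(s) {
      sm <- readBrainVolume(file.path(outDir,
        sprintf("sub%02d_%s_%s_sessions.nii.gz", s,
                specs[[nm]]$Tplus@condition, sp)), NULL)
      maps <- lapply(1:5, function(k) array(sm$data[, , , k], brain@dim))
      applyAnchoredContrast(maps, specs[[nm]]$Tplus)
    })
    f <- file.path(outDir, sprintf("contrast_%s_%s.nii.gz", nm, sp))
    writeBrainVolume(array(unlist(vols), c(brain@dim,
                                           length(vols))), f, brain)
    files <- c(files, f)
  }
  writeManifest(outDir, "contrasts", run$seed, hash, files)
}

stageGroup <- function(outDir, run, hash) {
  readManifest(outDir, "contrasts", "group")
  coh <- cohortFromManifest(outDir, run, "group")
  brain <- toyBrain(run$generator$brain$dim, run$generator$brain$voxelMm)
  specNames <- c("CxS_SD", "C_on_SD", "C_on_NP", "S_minus_C_SD")
  files <- character()
  peaks <- list()
  for (sp in c("fast", "slow")) {
    stat <- list()
    for (nm in specNames) {
      v <- readBrainVolume(file.path(outDir,
        sprintf("contrast_%s_%s.nii.gz", nm, sp)), NULL)$data
      maps <- lapply(seq_len(dim(v)[4L]), function(k)
        array(v[, , , k], brain@dim))
      for (dir in c("Tplus", "Tminus")) {
        m <- if (dir == "Tplus") maps else lapply(maps, function(x) -x)
        stat[[paste(nm, dir, sep = "_")]] <-
          permutationFwe(m, brain, "onesample", nPerm = run$nPerm,
                         seed = childSeed(run$seed,
                                          paste0("grp-", nm, sp, dir)))
      }
    }
    for (key in names(stat)) {
      f <- file.path(outDir, sprintf("stat_%s_%s_t.nii.gz", key, sp))
      writeBrainVolume(ifelse(is.na(stat[[key]]@t), 0, stat[[key]]@t),
                       f, brain)
      files <- c(files, f)
      pt <- peakTable(stat[[key]], run$alpha)
      if (nrow(pt))
        peaks[[length(peaks) + 1L]] <-
          cbind(contrast = key, speed = sp, pt)
    }
  }
  fPeaks <- file.path(outDir, "peak_tables.tsv")
  if (length(peaks)) writeTsv(do.call(rbind, peaks), fPeaks)
  else writeTsv(data.frame(contrast = character()), fPeaks)
  files <- c(files, fPeaks)
  writeManifest(outDir, "group", run$seed, hash, files)
}

stageReport <- function(outDir, run, hash) {
  for (st in c("behavior", "markers", "group"))
    readManifest(outDir, st, "report")
  beh <- readTsv(file.path(outDir, "behavioral_summary.tsv"))
  mk <- readTsv(file.path(outDir, "markers.tsv"))
  pk <- readTsv(file.path(outDir, "peak_tables.tsv"))
  f <- file.path(outDir, "report.txt")
  con <- file(f, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("chronoVigil pipeline report (seed ", run$seed,
           ", config ", substr(hash, 1, 8), ")"),
    "",
    sprintf("Subjects: %d  Permutations: %d  alpha: %g",
            run$nSubjects, run$nPerm, run$alpha),
    "",
    sprintf("Grand-mean KSS  SD: %.2f   NP: %.2f",
            mean(beh$kss_mean[beh$condition == "SD"]),
            mean(beh$kss_mean[beh$condition == "NP"])),
    sprintf("Mean lapses (SD, by session): %s",
            paste(sprintf("%.1f", beh$lapses_mean[beh$condition == "SD"]),
                  collapse = " ")),
    sprintf("Marker table: %d subjects, %d excluded",
            nrow(mk), sum(mk$excluded)),
    sprintf("Significant FWE peaks: %d", nrow(pk))), con)
  writeManifest(outDir, "report", run$seed, hash, f)
}
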