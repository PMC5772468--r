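tinyBrain <- toyBrain(c(8L, 8L, 8L))

test_that("one-sample t matches the hand formula", {
  V <- prod(tinyBrain@dim)
  X <- matrix(0, 3, V)
  X[, 1] <- c(1, 2, 3)
  sm <- suppressMessages(oneSampleT(X, tinyBrain))
  expect_equal(sm@t[1], 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(as.numeric(sm@t[1]), 3.4641016, tolerance = 1e-6)
  expect_equal(sm@df, 2)
  # all-zero maps: zero variance everywhere -> NA
  smZ <- suppressMessages(oneSampleT(matrix(0, 3, V), tinyBrain))
  expect_true(all(is.na(smZ@t)))
  # sign flip negates t
  smN <- suppressMessages(oneSampleT(-X, tinyBrain))
  expect_equal(smN@t[1], -sm@t[1])
})

test_that("covariate slope t handles exact fits, orthogonality and errors", {
  V <- prod(tinyBrain@dim)
  cv <- c(1, 2, 3, 4, 5, 6)
  X <- matrix(rep(2 * cv, V), 6, V)  # exact linear relation everywhere
  sm <- covariateSlopeT(X, cv, tinyBrain)
  expect_equal(sm@df, 4)
  expect_true(all(sm@t[!is.na(sm@t)] == 1e6))
  expect_true(sm@provenance$cappedPerfectFit)
  expect_error(covariateSlopeT(X, rep(2, 6), tinyBrain), "constant")
  # orthogonal covariate: slope t centred on zero
  set.seed(3)
  Y <- matrix(rnorm(12 * V), 12, V)
  smO <- covariateSlopeT(Y, rnorm(12), tinyBrain)
  expect_lt(abs(mean(smO@t)), 0.1)
  # NA covariates (excluded subjects) are dropped
  cv2 <- c(NA, rnorm(11))
  smNA <- covariateSlopeT(Y, cv2, tinyBrain)
  expect_equal(smNA@provenance$n, 11)
})

test_that("small samples trigger exhaustive sign enumeration", {
  V <- prod(tinyBrain@dim)
  set.seed(8)
  X <- matrix(rnorm(4 * V), 4, V)
  expect_warning(sm <- permutationFwe(X, tinyBrain, nPerm = 500, seed = 1),
                 "16 exhaustively")
  expect_equal(sm@provenance$nPerm, 15)
  p <- sm@pFwe[!is.na(sm@pFwe)]
  expect_gte(min(p), 1 / 16)
  # a single overwhelming voxel attains the minimum achievable p
  X[, 1] <- X[, 1] / 100 + 50
  expect_warning(sm2 <- permutationFwe(X, tinyBrain, nPerm = 500, seed = 1))
  expect_equal(sm2@pFwe[1], 1 / 16)
})

test_that("a planted strong voxel reaches the minimum achievable p", {
  V <- prod(tinyBrain@dim)
  set.seed(12)
  X <- matrix(rnorm(12 * V), 12, V)
  X[, 5] <- abs(X[, 5]) / 10 + 20
  sm <- permutationFwe(X, tinyBrain, nPerm = 600, seed = 2)
  expect_equal(sm@pFwe[5], 1 / 601, tolerance = 1e-12)
  expect_error(permutationFwe(X, tinyBrain, nPerm = 100), "500")
})

test_that("ROI small-volume correction restricts the maxT family", {
  V <- prod(tinyBrain@dim)
  set.seed(4)
  X <- matrix(rnorm(10 * V), 10, V)
  whole <- permutationFwe(X, tinyBrain, nPerm = 500, seed = 9)
  roiAll <- roiSmallVolume(X, tinyBrain, array(TRUE, tinyBrain@dim),
                           nPerm = 500, seed = 9)
  expect_equal(roiAll@pFwe, whole@pFwe)
  # a subthreshold effect becomes significant within its small ROI
  thal <- regionMask(toyBrain(c(8L, 8L, 8L)), "thalamus")
  X2 <- X
  X2[, thal] <- X2[, thal] + 1.6
  wb <- permutationFwe(X2, tinyBrain, nPerm = 500, seed = 9)
  svc <- roiSmallVolume(X2, tinyBrain, thal, nPerm = 500, seed = 9)
  expect_lte(min(svc@pFwe[thal], na.rm = TRUE),
             min(wb@pFwe[thal], na.rm = TRUE))
  expect_true(all(is.na(svc@pFwe[!thal])))
  expect_error(roiSmallVolume(X, tinyBrain, array(FALSE, tinyBrain@dim),
                              nPerm = 500), "empty")
})

test_that("exclusive masking removes shared voxels and flags the survivors", {
  V <- prod(tinyBrain@dim)
  set.seed(6)
  X <- matrix(rnorm(12 * V), 12, V)
  X[, 1:30] <- X[, 1:30] + 4
  primary <- permutationFwe(X, tinyBrain, nPerm = 500, seed = 3)
  # other identical to primary: every significant voxel is masked out
  self <- exclusiveMask(primary, primary)
  expect_equal(nrow(peakTable(self)), 0L)
  # other all-null: primary is unchanged where significant
  null <- suppressMessages(oneSampleT(matrix(rnorm(12 * V, -5), 12, V),
                                      tinyBrain))
  kept <- exclusiveMask(primary, null)
  expect_equal(kept@pFwe[primary@mask & kept@mask],
               primary@pFwe[primary@mask & kept@mask])
  pk <- peakTable(kept)
  expect_gt(nrow(pk), 0)
  expect_true(all(pk$speed_specific))
})

test_that("peak tables label, localise and order local maxima", {
  brain <- toyBrain(c(12L, 14L, 12L))
  V <- prod(brain@dim)
  set.seed(10)
  X <- matrix(rnorm(14 * V, 0, 0.3), 14, V)
  thal <- regionMask(brain, "thalamus")
  ling <- regionMask(brain, "lingual")
  X[, thal] <- X[, thal] + 6
  X[, ling] <- X[, ling] + 3.5
  sm <- permutationFwe(X, brain, nPerm = 500, seed = 5)
  pk <- peakTable(sm)
  expect_gt(nrow(pk), 1)
  expect_equal(pk$region[1], "thalamus")
  # both planted regions appear (incidental alpha-level false positives
  # elsewhere are permitted)
  expect_true(all(c("thalamus", "lingual") %in% pk$region))
  expect_true(!is.unsorted(pk$p_fwe))
  expect_true(all(pk$side %in% c("L", "R", "B")))
  # mm coordinates come from the affine
  mmAll <- voxelToMm(brain, which(thal, arr.ind = TRUE) - 1)
  row <- pk[pk$region == "thalamus", ][1, ]
  expect_true(row$x >= min(mmAll[, 1]) && row$x <= max(mmAll[, 1]))
  # Z equivalents: standard-normal quantile of the t tail
  expect_equal(row$z, chronoVigil:::tToZ(row$t, sm@df), tolerance = 1e-9)
  # no significant voxels -> empty table
  null <- permutationFwe(matrix(rnorm(14 * V), 14, V), brain,
                         nPerm = 500, seed = 6)
  expect_equal(nrow(peakTable(null)), 0L)
  expect_error(peakTable(suppressMessages(oneSampleT(X, brain))),
               "no FWE")
})

test_that("marker-coupled amplitudes are recovered by covariate inference", {
  # higher planted delta rebound -> stronger cortical (frontal) decline
  cfg <- smallBrainConfig()
  brain <- toyBrain(cfg$brain$dim, cfg$brain$voxelMm)
  hits <- logical(4)
  for (cs in 1:4) {
    coh <- simulateCohort(16, cfg, seed = 400 + cs)
    maps <- lapply(1:16, function(s)
      subjectContrastMaps(coh, s, "SD", "fast", brain)$fast)
    specs <- makeContrastSpecs(sleepinessProfile(coh, "SD"),
                               sleepinessProfile(coh, "NP"))
    tm <- lapply(maps, applyAnchoredContrast, spec = specs$CxS_SD$Tminus)
    reb <- subjects(coh)$deltaReboundTrue
    reb[flagLowOutliers(reb)] <- NA
    sm <- permutationFwe(tm, brain, "slope", covariate = reb, nPerm = 500,
                         seed = cs)
    hits[cs] <- any(sm@pFwe[regionMask(brain, "frontal")] <= 0.05,
                    na.rm = TRUE)
  }
  expect_gte(sum(hits), 3)
})
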