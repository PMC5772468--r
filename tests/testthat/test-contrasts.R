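calibratedSpecs <- function(speed = "fast") {
  lp <- latentProfiles()
  makeContrastSpecs(profileFromMeans("SD", lp$sd),
                    profileFromMeans("NP", lp$np), speed = speed)
}

test_that("all contrast weights sum to zero and T- negates T+", {
  specs <- calibratedSpecs()
  for (nm in names(specs)) {
    expect_lt(abs(sum(contrastWeights(specs[[nm]]$Tplus))), 1e-10)
    expect_equal(contrastWeights(specs[[nm]]$Tminus),
                 -contrastWeights(specs[[nm]]$Tplus))
  }
})

test_that("contrasts apply to the documented protocol arms", {
  specs <- calibratedSpecs()
  expect_equal(condition(specs$CxS_SD$Tplus), "SD")
  expect_equal(condition(specs$C_on_SD$Tplus), "SD")
  expect_equal(condition(specs$C_on_NP$Tplus), "NP")
  expect_equal(condition(specs$S_minus_C_SD$Tplus), "SD")
  # circadian weights are shared between the two arms they are applied to
  expect_equal(contrastWeights(specs$C_on_SD$Tplus),
               contrastWeights(specs$C_on_NP$Tplus))
})

test_that("the calibrated interaction weights peak at the night session", {
  specs <- calibratedSpecs()
  expect_equal(which.max(contrastWeights(specs$CxS_SD$Tplus)), 3L)
})

test_that("the homeostatic difference weights rise monotonically with time awake", {
  w <- contrastWeights(calibratedSpecs()$S_minus_C_SD$Tplus)
  expect_true(all(diff(w) > 0))
  expect_equal(cor(w, 1:5, method = "spearman"), 1)
})

test_that("coinciding profiles degrade the difference contrast with a flag", {
  lp <- latentProfiles()
  pr <- profileFromMeans("SD", lp$sd)
  expect_warning(specs <- makeContrastSpecs(pr, pr), "degenerate")
  expect_true(specs$S_minus_C_SD$Tplus@degenerate)
  expect_lt(max(abs(contrastWeights(specs$S_minus_C_SD$Tplus))), 1e-10)
})

test_that("gapped profiles are refused until validated", {
  lp <- latentProfiles()
  gap <- lp$sd; gap[2] <- NA
  pr <- new("SleepinessProfile", condition = "SD", meanKss = gap,
            zWeights = c(zscoreProfile(gap[-2]), NA)[c(1, 5, 2, 3, 4)],
            nSubjects = rep(30L, 5L))
  expect_error(makeContrastSpecs(pr, profileFromMeans("NP", lp$np)),
               "missing sessions")
})

test_that("anchored contrasts are weighted sums with offset invariance", {
  specs <- calibratedSpecs()
  spec <- specs$CxS_SD$Tplus
  dims <- c(6L, 6L, 6L)
  vals <- c(2, -1, 4, 0.5, 3)
  maps <- lapply(vals, function(v) array(v, dims))
  out <- applyAnchoredContrast(maps, spec)
  expect_equal(out, array(sum(contrastWeights(spec) * vals), dims),
               tolerance = 1e-12)
  # adding a session-constant c changes nothing (weights sum to zero)
  maps2 <- lapply(maps, function(m) m + 11.3)
  expect_equal(applyAnchoredContrast(maps2, spec), out, tolerance = 1e-9)
  # simple two-session difference
  w2 <- new("ContrastSpec", name = "CxS_SD", condition = "SD",
            weights = c(1, -1, 0, 0, 0), direction = "T+", speed = "fast",
            degenerate = FALSE)
  m <- lapply(c(7, 3, 0, 0, 0), function(v) array(v, dims))
  expect_equal(applyAnchoredContrast(m, w2), array(4, dims))
})

test_that("maps proportional to the weights maximise the contrast in their region", {
  specs <- calibratedSpecs()
  spec <- specs$CxS_SD$Tplus
  w <- contrastWeights(spec)
  brain <- toyBrain(c(12L, 14L, 12L))
  thal <- regionMask(brain, "thalamus")
  maps <- lapply(seq_len(5), function(s) {
    m <- array(0.2 * sin(s), brain@dim)       # arbitrary background
    m[thal] <- 2 * w[s]                       # aligned profile
    m
  })
  out <- applyAnchoredContrast(maps, spec)
  expect_equal(max(out), out[which(thal)[1]], tolerance = 1e-9)
  expect_equal(out[which(thal)[1]], 2 * sum(w^2), tolerance = 1e-9)
})

test_that("a validated missing session re-standardises the weights", {
  specs <- calibratedSpecs()
  spec <- specs$CxS_SD$Tplus
  dims <- c(6L, 6L, 6L)
  maps <- lapply(1:5, function(s) array(s, dims))
  maps4 <- maps; maps4[2] <- list(NULL)
  out <- applyAnchoredContrast(maps4, spec)
  w <- spec@weights[-2]
  w <- w - mean(w)
  w <- w / sqrt(mean(w^2)) * sqrt(mean(spec@weights^2))
  expect_equal(out[1], sum(w * c(1, 3, 4, 5)), tolerance = 1e-9)
  expect_error(applyAnchoredContrast(maps[1:3], spec), "length")
  bad <- maps; bad[[5]] <- array(1, c(5L, 5L, 5L))
  expect_error(applyAnchoredContrast(bad, spec), "geometries")
})
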