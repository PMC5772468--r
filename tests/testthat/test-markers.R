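# Reduced EEG coefficients keep the spectral unit tests fast while the
# acceptance suite exercises the full-night defaults.
fastEeg <- function() {
  co <- defaultEegCoeffs()
  co$epochsPerNight <- 120L
  co$nightMix <- c(W = 5L, N1 = 10L, N2 = 55L, N3 = 25L, N4 = 10L,
                   R = 15L)
  co
}

eegParams <- function(baseline = 400, rebound = 100) {
  p <- defaultSubjectParams()
  p$deltaBaselineTrue <- baseline
  p$deltaReboundTrue <- rebound
  p
}

test_that("a pure on-bin tone has the closed-form Hanning band power", {
  fs <- 64; n <- fs * 30
  a <- 4
  tt <- (seq_len(n) - 1) / fs
  for (f0 in c(1, 2, 3.5)) {
    x <- a * cos(2 * pi * f0 * tt + 0.7)
    sp <- hanningSpectrum(x, fs)
    band <- sp$freq >= 0.7 & sp$freq <= 4
    expect_equal(sum(sp$power[band]), 0.75 * a^2, tolerance = 1e-8)
  }
})

test_that("white-noise band power matches the flat-spectrum expectation", {
  fs <- 64; n <- fs * 30
  set.seed(5)
  tot <- band <- 0
  for (i in 1:10) {
    sp <- hanningSpectrum(rnorm(n), fs)
    sel <- sp$freq >= 0.7 & sp$freq <= 4
    tot <- tot + sum(sp$power)
    band <- band + sum(sp$power[sel])
  }
  expect_equal(band / tot, sum(sp$freq >= 0.7 & sp$freq <= 4) /
                 length(sp$freq), tolerance = 0.1)
})

test_that("delta power averages artifact-free NREM epochs only", {
  sp <- simulateSleepEeg(eegParams(), "baseline", fastEeg(), seed = 2)
  expect_error(nremDeltaPower(sp, stages = rep(6L, length(sp$stages))),
               "no artifact-free NREM")
  # epoch order is irrelevant
  perm <- sample(length(sp$stages))
  sp2 <- sp
  sp2$power <- sp$power[perm, ]; sp2$stages <- sp$stages[perm]
  sp2$rms <- sp$rms[perm]
  expect_equal(nremDeltaPower(sp), nremDeltaPower(sp2))
  expect_error(nremDeltaPower(sp, stages = sp$stages[-1]), "not aligned")
})

test_that("planted night-level delta power is recovered", {
  co <- fastEeg()
  est <- vapply(1:6, function(s)
    nremDeltaPower(simulateSleepEeg(eegParams(400, 0), "baseline", co,
                                    seed = s)), numeric(1))
  # white-noise floor in the band is common to all epochs and nights
  floorP <- 3 * co$sigmaWhite^2 / (co$fs * 30) *
    sum(seq_len(co$fs * 15 - 1) / 30 >= 0.7 & seq_len(co$fs * 15 - 1) / 30 <= 4)
  expect_equal(mean(est) - floorP, 400, tolerance = 25)
})

test_that("the rebound is recovery minus baseline and cancels the noise floor", {
  expect_equal(deltaRebound(100, 160), 60)
  expect_equal(deltaRebound(77, 77), 0)
  co <- fastEeg()
  p <- eegParams(450, 120)
  reb <- vapply(1:6, function(s)
    deltaRebound(
      nremDeltaPower(simulateSleepEeg(p, "baseline", co, seed = s)),
      nremDeltaPower(simulateSleepEeg(p, "recovery", co, seed = s + 50))),
    numeric(1))
  expect_equal(mean(reb), 120, tolerance = 20)
})

test_that("the 2-IQR rule flags exactly the gross low outlier", {
  flags <- flagLowOutliers(c(1.0, 1.1, 1.2, 1.3, -5))
  expect_identical(flags, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_false(any(flagLowOutliers(rep(2.5, 6))))
  expect_error(flagLowOutliers(1:4), "at least 5")
})

test_that("composite circadian strength follows the stated percentage convention", {
  np <- protocolSchedule("NP")
  H <- matrix(3L, 10, 160)              # fully asleep in N2
  H[1, 1:40] <- 1L                      # nap 1: 40 wake epochs
  H[1, 41:70] <- 6L                     # 30 REM of 120 sleep = 25%
  H[4, 1:80] <- 1L                      # evening nap: 50% wake
  expect_equal(circadianStrength(H, np), 75)
  # ordering of non-evening naps is irrelevant
  H2 <- H[c(2, 1, 3:10), ]
  expect_equal(circadianStrength(H2, np), 75)
  expect_equal(circadianStrength(matrix(3L, 10, 160), np), 0)
  expect_error(circadianStrength(H[1:9, ], np), "match")
})

test_that("Spearman correlation handles monotone, anti-monotone and constant input", {
  x <- c(1, 3, 4, 7, 9, 12)
  expect_equal(remSleepinessCorrelation(x, exp(x))$r, 1)
  expect_equal(remSleepinessCorrelation(x, -x^3)$r, -1)
  expect_error(remSleepinessCorrelation(rep(1, 6), x), "constant")
  expect_error(remSleepinessCorrelation(x[1:3], x[1:3]), "at least 5")
})

test_that("the marker table excludes flagged subjects from covariate use", {
  coh <- smallCohort(3)
  cfg <- coh@config$eeg
  cfg$epochsPerNight <- 120L
  cfg$nightMix <- c(W = 5L, N1 = 10L, N2 = 55L, N3 = 25L, N4 = 10L,
                    R = 15L)
  mt <- markerTable(coh, cfg)
  sub <- subjects(coh)
  out <- which(sub$deltaReboundTrue < -200)
  expect_true(mt$excluded[out])
  expect_true(is.na(mt$delta_rebound[out]))
  expect_match(mt$reason[out], "IQR")
  expect_equal(sum(!mt$excluded), nrow(sub) - 1L)
  expect_true(all(is.finite(mt$circ_strength)))
})
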