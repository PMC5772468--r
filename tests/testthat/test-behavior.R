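test_that("session sleepiness is the pre/post mean with single-rating fallback", {
  expect_equal(sessionKss(5, 7), 6)
  expect_equal(sessionKss(4, 4), 4)
  v <- sessionKss(3, NA)
  expect_equal(as.numeric(v), 3)
  expect_true(attr(v, "singleRating"))
  expect_true(is.na(sessionKss(NA, NA)))
  expect_error(sessionKss(0, 5), "\\[1, 9\\]")
})

test_that("z-scored profiles have population mean 0 / SD 1 and known values", {
  z <- zscoreProfile(1:5)
  expect_equal(z, c(-sqrt(2), -sqrt(2) / 2, 0, sqrt(2) / 2, sqrt(2)),
               tolerance = 1e-12)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
})

test_that("z-scoring is invariant to affine transforms and preserves order", {
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(5, 5, 2)
    a <- runif(1, 0.1, 4); b <- runif(1, -10, 10)
    expect_equal(zscoreProfile(a * x + b), zscoreProfile(x),
                 tolerance = 1e-10)
    expect_identical(order(zscoreProfile(x)), order(x))
  }
  expect_error(zscoreProfile(rep(3, 5)), "constant")
})

test_that("strictly increasing profiles give strictly increasing weights", {
  set.seed(1)
  for (i in 1:10) {
    x <- cumsum(runif(5, 0.1, 2))
    expect_true(all(diff(zscoreProfile(x)) > 0))
  }
})

test_that("RT partition reproduces the interpolation-percentile oracle", {
  part <- partitionRts(c(200, 220, 240, 260, 280, 300, 320, 340))
  expect_equal(part$p25, 235)
  expect_equal(part$p75, 305)
  expect_equal(part$rts[part$labels == "fast"], c(200, 220))
  expect_equal(part$rts[part$labels == "slow"], c(320, 340))
  expect_equal(sum(part$labels == "intermediate"), 4L)
})

test_that("degenerate and lapse-bearing partitions follow the stated rules", {
  allSame <- partitionRts(rep(250, 8))
  expect_true(all(allSame$labels == "intermediate"))
  withLapse <- partitionRts(c(200, 220, 240, 260, 280, 300, 320, 340, 620))
  expect_equal(withLapse$rts[withLapse$labels == "lapse"], 620)
  # the lapse is excluded from percentile computation
  expect_equal(withLapse$p25, 235)
  expect_equal(withLapse$p75, 305)
  expect_error(partitionRts(c(200, 250)), "fewer than 8")
})

test_that("partition counts are balanced and conserve trials", {
  set.seed(9)
  for (i in 1:10) {
    n <- sample(24:60, 1)
    rts <- runif(n, 200, 480)  # lapse-free
    part <- partitionRts(rts)
    tab <- table(part$labels)
    expect_lte(abs(tab[["fast"]] - floor(n / 4)), 1)
    expect_lte(abs(tab[["slow"]] - floor(n / 4)), 1)
    expect_equal(sum(tab), n)
  }
})

test_that("behavioural summary conserves trial counts and detects no effect in identical arms", {
  coh <- smallCohort(1)
  tab <- behavioralSummary(coh, nPerm = 200, seed = 1)
  expect_equal(nrow(tab), 10L)
  p <- pvtTrials(coh)
  for (ses in c(1, 4)) {
    rts <- p[p$condition == "SD" & p$session == ses &
             p$trial_type == "clock", ]
    counts <- vapply(split(rts$response_time_ms, rts$subject), function(r) {
      part <- partitionRts(r)
      sum(table(part$labels)) == length(r)
    }, logical(1))
    expect_true(all(counts))
  }
  # SD should carry the condition effect at the night session
  expect_lt(tab$p_cond_kss[tab$condition == "SD" & tab$session == 3], 0.05)
})

test_that("missing-session inclusion check follows the correlation rule", {
  ref <- c(4, 5, 7, 6.5, 6)
  expect_true(missingSessionCheck(ref, ref))
  expect_false(missingSessionCheck(rev(ref), ref))
  gap <- ref; gap[2] <- NA
  expect_true(missingSessionCheck(gap, ref))
  twoLeft <- c(4, NA, NA, NA, 6)
  expect_warning(ok <- missingSessionCheck(twoLeft, ref), "fewer than 3")
  expect_false(ok)
})
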