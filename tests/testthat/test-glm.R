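test_that("the canonical HRF has the expected shape", {
  dt <- 0.01
  h <- canonicalHrf(dt)
  tt <- seq(0, 32, by = dt)
  expect_equal(h[1], 0)
  peak <- tt[which.max(h)]
  expect_gt(peak, 4.7)
  expect_lt(peak, 5.3)
  expect_equal(max(h), 1)
  expect_gt(sum(h) * dt, 0)          # positive net response
  expect_lt(min(h), 0)               # undershoot present
})

test_that("a single event regressor reproduces the sampled HRF", {
  tr <- 2.2; nScans <- 60
  reg <- chronoVigil:::eventRegressor(0, nScans, tr)
  h <- canonicalHrf(0.1)
  idx <- floor((0:(nScans - 1)) * tr / 0.1) + 1
  expected <- numeric(nScans)
  within <- idx <= length(h)
  expected[within] <- h[idx[within]]
  expect_equal(reg, expected, tolerance = 1e-8)
})

test_that("design matrices have the documented layout and are deterministic", {
  pvt <- fixturePvt()
  clock <- pvt[pvt$trial_type == "clock", ]
  part <- partitionRts(clock$response_time_ms)
  d1 <- buildDesign(pvt, part)
  d2 <- buildDesign(pvt, part)
  expect_identical(d1, d2)
  types <- levels(part$labels)[table(part$labels) > 0]
  expect_equal(ncol(d1$matrix),
               2 * length(types) + 6 + floor(2 * 273 * 2.2 / 128) + 1)
  expect_true(all(c("fast", "fast_tmod", "motion1", "dct1", "intercept")
                  %in% colnames(d1$matrix)))
})

test_that("absent event types are dropped with a message", {
  onsets <- seq(5, 595, by = 12)
  pvt <- data.frame(onset_s = onsets, trial_type = "clock",
                    response_time_ms = seq(220, 420,
                                           length.out = length(onsets)))
  part <- partitionRts(pvt$response_time_ms)
  expect_true(sum(part$labels == "lapse") == 0)
  expect_message(d <- buildDesign(pvt, part), "lapse")
  expect_false("lapse" %in% colnames(d$matrix))
  expect_identical(d$dropped, "lapse")
})

test_that("OLS betas match the normal-equation oracle", {
  set.seed(21)
  n <- 10
  X <- cbind(fast = rnorm(n), slow = rnorm(n), intercept = 1)
  Y <- matrix(rnorm(n * 3), n, 3)
  brain <- toyBrain(c(8L, 8L, 8L))
  fit <- fitGlm(list(data = Y, brain = brain), list(matrix = X))
  oracle <- solve(t(X) %*% X) %*% t(X) %*% Y
  expect_equal(unname(fit@betas), unname(oracle), tolerance = 1e-8)
  expect_equal(fit@df, n - 3L)
  rss <- colSums((Y - X %*% oracle)^2)
  expect_equal(fit@sigma2, unname(rss / (n - 3)), tolerance = 1e-8)
})

test_that("rank-deficient designs fail naming the collinear columns", {
  n <- 12
  X <- cbind(a = rnorm(n), b = 1, intercept = 1)
  expect_error(fitGlm(list(data = matrix(rnorm(n * 2), n, 2),
                           brain = toyBrain(c(8L, 8L, 8L))),
                      list(matrix = X)),
               "rank deficient.*(b|intercept)")
})

test_that("noise-free forward simulation is recovered exactly", {
  brain <- toyBrain(c(12L, 14L, 12L))
  pvt <- fixturePvt()
  bl <- simulateBold(pvt, brain, flatPlanted(amp = 1), session = 1,
                     coeffs = noiselessBold(), seed = 1)
  fit <- fitGlm(bl, buildDesign(pvt, bl$partition, bl$motion))
  beta <- sessionContrast(fit, "fast")
  thal <- regionMask(brain, "thalamus")
  expect_equal(unname(beta[thal]), rep(1, sum(thal)), tolerance = 1e-6)
  expect_equal(max(abs(beta[!thal])), 0, tolerance = 1e-6)
  slow <- sessionContrast(fit, "slow")
  expect_equal(max(abs(slow)), 0, tolerance = 1e-6)
})

test_that("GLM residuals are orthogonal to the design", {
  pvt <- fixturePvt()
  brain <- toyBrain(c(8L, 8L, 8L))
  co <- defaultBoldCoeffs()
  bl <- simulateBold(pvt, brain, flatPlanted(amp = 0.5), coeffs = co,
                     seed = 9)
  des <- buildDesign(pvt, bl$partition, bl$motion)
  fit <- fitGlm(bl, des)
  res <- bl$data - des$matrix %*% fit@betas
  expect_lt(max(abs(t(des$matrix) %*% res)) / nrow(res), 1e-6)
})

test_that("estimation is equivariant under scaling and ignores empty planted types", {
  pvt <- fixturePvt()
  brain <- toyBrain(c(12L, 14L, 12L))
  bl <- simulateBold(pvt, brain, flatPlanted(amp = 1), coeffs = noiselessBold(),
                     seed = 1)
  des <- buildDesign(pvt, bl$partition, bl$motion)
  f1 <- fitGlm(bl, des)
  bl2 <- bl; bl2$data <- 3 * bl$data
  f2 <- fitGlm(bl2, des)
  expect_equal(3 * f1@betas, f2@betas, tolerance = 1e-9)
  # adding a zero-amplitude planted type leaves other betas unchanged
  pl <- rbind(flatPlanted(amp = 1), flatPlanted("lingual", "slow", 0))
  bl3 <- simulateBold(pvt, brain, pl, coeffs = noiselessBold(), seed = 1)
  f3 <- fitGlm(bl3, des)
  expect_equal(f1@betas["fast", ], f3@betas["fast", ], tolerance = 1e-6)
})

test_that("unknown planted regions are rejected", {
  expect_error(simulateBold(fixturePvt(), toyBrain(c(8L, 8L, 8L)),
                            flatPlanted("amygdala")),
               "unknown region")
})

test_that("Gaussian smoothing has the stated kernel and invariances", {
  v <- array(0, c(17, 17, 17))
  expect_identical(smoothVolume(v + 2, 0), v + 2)
  expect_equal(smoothVolume(v + 2, 8, 3), v + 2, tolerance = 1e-12)
  delta <- v; delta[9, 9, 9] <- 1
  sm <- smoothVolume(delta, 8, 3)
  sigma <- 8 / (2 * sqrt(2 * log(2))) / 3
  r <- ceiling(3 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2)); k <- k / sum(k)
  # kernel fully interior (and away from the edge renormalisation):
  # the x-profile is the 1D kernel times the centre weights of y and z
  expect_equal(sm[9 + (-r:r), 9, 9], k * k[r + 1]^2, tolerance = 1e-10)
  expect_equal(sum(sm), 1, tolerance = 1e-10)  # interior mass preserved
})
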