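test_that("response coding averages hit/miss events within a volume", {
  ft <- (0:199) * 1.6
  # one hit and one miss inside the same volume cancel to 0
  ev <- data.frame(onset = c(10.1, 10.9), outcome = c(1, 0))
  r <- codeResponses(ev, ft)
  expect_equal(r[7], 0)
  expect_equal(sum(r != 0), 0)
  # lone hit codes 0.5, lone miss -0.5
  r2 <- codeResponses(data.frame(onset = c(3.3, 20.0), outcome = c(1, 0)), ft)
  expect_equal(sort(unique(r2)), c(-0.5, 0, 0.5))
  # no events: identically zero
  expect_true(all(codeResponses(NULL, ft) == 0))
})

test_that("speech design has the five convolved conditions plus response", {
  sch <- simulateSpeechSchedule(nRuns = 1, seed = 2)
  blocks <- sch$blocks
  ft <- (0:319) * 1.6
  ev <- data.frame(onset = sch$events$onset[sch$events$isTarget][1:20],
                   outcome = rep(c(1, 0), 10))
  X <- speechDesign(blocks, ev, frameTimes = ft)
  nm <- colnames(designMatrix(X))
  expect_true(all(c("speech_vowel", "speech_consonant", "speaker_vowel",
                    "speaker_consonant", "instruction", "response") %in% nm))
  expect_equal(X@convolved[1:6], rep(TRUE, 6))
  expect_error(speechDesign(transform(blocks, task = 2), NULL,
                            frameTimes = ft), "unknown condition")
  # a 17 s block at TR 1.6 covers floor or ceiling of 17/1.6 volumes,
  # depending on its phase relative to the volume grid
  onset <- blocks$onset[1]
  nCover <- sum(ft >= onset & ft < onset + 17)
  expect_true(nCover %in% c(floor(17 / 1.6), ceiling(17 / 1.6)))
})

test_that("localizer design models sparse timing and drops repeats/nulls", {
  sch <- simulateLocalizerSchedule(84, repeatRate = 0, nullRate = 0, seed = 1)
  nVol <- max(sch$volume) + 4
  X <- localizerDesign(sch, nVol)
  expect_equal(frameTimes(X), (seq_len(nVol) - 1) * 2.8 + 0.8)
  # single sound: column equals the HRF sampled at the gap-aware times
  one <- data.frame(onset = 10.0)
  X1 <- localizerDesign(one, 20)
  expect_equal(designMatrix(X1)[, "sound"],
               hrfRegressor(10, 1, sparseFrameTimes(20)))
  # ~5% repeats excluded on average (expectation over seeds)
  kept <- vapply(1:60, function(s) {
    sc <- simulateLocalizerSchedule(84, repeatRate = 0.05, nullRate = 0,
                                    seed = s)
    sum(!sc$isRepeat & !sc$isNull)
  }, numeric(1))
  expect_equal(mean(kept), 84 * 0.95, tolerance = 0.01 * 84)
  # onset inside an acquisition window warns
  expect_warning(localizerDesign(data.frame(onset = 0.5), 10), "collide")
})

test_that("voxelwise OLS equals the normal-equations closed form", {
  set.seed(3)
  X <- cbind(1, rnorm(40), rnorm(40))
  B <- matrix(rnorm(3 * 7), 3)
  Y <- X %*% B
  fit <- fitGlm(Y, X)
  expect_lt(max(abs(t(fit@coefficients) - B)), 1e-8)
  expect_equal(fit@df, 40 - 3)
  closed <- solve(crossprod(X)) %*% crossprod(X, Y)
  expect_equal(t(fit@coefficients), closed, tolerance = 1e-10,
               ignore_attr = TRUE)
  # rank-deficient designs are rejected naming the dependent column
  Xbad <- cbind(a = X[, 1], b = X[, 2], c = X[, 2])
  expect_error(fitGlm(Y, Xbad), "rank-deficient")
  expect_error(fitGlm(Y, Xbad), "c")
})

test_that("GLM on a 4-D volume honours the mask and grid bookkeeping", {
  set.seed(4)
  d <- c(4, 4, 3); nT <- 30
  arr <- array(rnorm(prod(d) * nT), c(d, nT))
  X <- cbind(intercept = 1, reg = rnorm(nT))
  mask <- array(FALSE, d); mask[2:3, 2:3, 2] <- TRUE
  vol <- volumeImage(arr)
  fit <- fitGlm(vol, X, mask = mask)
  expect_equal(nrow(fit@coefficients), sum(mask))
  cm <- contrastMap(fit, c(0, 1))
  expect_true(is(cm$tVolume, "VolumeImage"))
  expect_equal(sum(!is.na(volData(cm$tVolume))), sum(mask))
})

test_that("contrasts reproduce textbook t statistics", {
  set.seed(5)
  Y <- matrix(rnorm(25 * 6, mean = 0.4), 25)
  fit <- fitGlm(Y, matrix(1, 25, 1))
  cm <- contrastMap(fit, 1)
  tt <- apply(Y, 2, function(v) unname(t.test(v)$statistic))
  expect_equal(cm$t, tt, tolerance = 1e-12)
  expect_equal(cm$df, 24)
  # zero weights give a zero map
  expect_true(all(contrastMap(fit, 0)$effect == 0))
  # adding a constant confound does not move condition contrasts
  X2 <- cbind(cond = rep(c(1, 0), length.out = 25), intercept = 1)
  f2 <- fitGlm(Y, X2)
  Y3 <- Y + 7
  f3 <- fitGlm(Y3, X2)
  expect_equal(contrastMap(f2, c(1, 0))$effect,
               contrastMap(f3, c(1, 0))$effect, tolerance = 1e-10)
  # named weights resolve against design columns
  expect_equal(contrastMap(f2, c(cond = 1))$effect,
               contrastMap(f2, c(1, 0))$effect)
})

test_that("speech-vs-speaker weights average over change type", {
  sch <- simulateSpeechSchedule(nRuns = 1, seed = 6)
  ft <- (0:319) * 1.6
  set.seed(6)
  tg <- sch$events[sch$events$isTarget, ]
  ev <- data.frame(onset = tg$onset, outcome = rbinom(nrow(tg), 1, 0.8))
  X <- speechDesign(sch$blocks, ev, frameTimes = ft)
  betaTrue <- c(2, 1.4, 0.5, 0.1, 0.3, 0, 1)   # conditions..., resp, icpt
  y <- designMatrix(X) %*% betaTrue + rnorm(320, 0, 0.01)
  fit <- fitGlm(cbind(y), X)
  w <- c(0.5, 0.5, -0.5, -0.5, 0, 0, 0)
  cm <- contrastMap(fit, w)
  expect_equal(cm$effect,
               mean(betaTrue[1:2]) - mean(betaTrue[3:4]), tolerance = 0.05)
})

test_that("null GLM t statistics follow Student t", {
  set.seed(7)
  nT <- 20
  X <- cbind(1, rnorm(nT))
  ts <- replicate(300, {
    fitv <- fitGlm(matrix(rnorm(nT * 4), nT), X)
    contrastMap(fitv, c(0, 1))$t
  })
  expect_gt(ks.test(as.vector(ts), pt, df = nT - 2)$p.value, 0.001)
})

test_that("sparse sampling has no off-by-one in the silent gap", {
  # moving the gap (frame times) shifts the sampled HRF consistently
  on <- 7.3
  ftA <- sparseFrameTimes(20)
  ftB <- ftA + 0.4
  a <- hrfRegressor(on, 1, ftA, dt = 0.01)
  b <- hrfRegressor(on, 1, ftB, dt = 0.01)
  expect_equal(b, canonicalHrf(ftB - on), tolerance = 0.02)
  expect_equal(a, canonicalHrf(ftA - on), tolerance = 0.02)
})

test_that("Gaussian smoothing preserves constants and reduces variance", {
  set.seed(8)
  v <- volumeImage(array(rnorm(16^3), c(16, 16, 16)))
  sm <- smoothVolume(v, fwhm = 2)
  expect_lt(sd(volData(sm)), sd(volData(v)))
  const <- smoothVolume(volumeImage(array(3, c(8, 8, 8))), fwhm = 2)
  expect_equal(volData(const), array(3, c(8, 8, 8)), tolerance = 1e-10)
})
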