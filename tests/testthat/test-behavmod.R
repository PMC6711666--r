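test_that("HPD intervals are the narrowest contiguous mass", {
  expect_equal(hpd(rep(3.3, 200)), c(3.3, 3.3), ignore_attr = TRUE)          # point mass
  set.seed(1)
  u <- runif(2e5)
  expect_equal(diff(hpd(u, 0.97)), 0.97, tolerance = 0.01)
  # skewed draws: HPD is narrower than the central interval
  x <- rexp(2e5)
  ivH <- hpd(x, 0.9)
  ivQ <- quantile(x, c(0.05, 0.95))
  expect_lt(diff(ivH), diff(ivQ))
  expect_equal(ivH[1], 0, tolerance = 0.01)
  expect_error(hpd(rnorm(10)), "at least 100")
  # multimodal draws still yield a contiguous interval, with a note
  bim <- c(rnorm(5e4, -10, 0.1), rnorm(5e4, 10, 0.1))
  iv <- hpd(bim, 0.97)
  expect_true(attr(iv, "multimodal"))
  expect_lt(iv[1], -9)
  expect_gt(iv[2], 9)
})

test_that("task hit rates transform the posterior by closed form", {
  # degenerate all-zero posterior: (0.5, 0.5, 0)
  p0 <- taskHitRates(pointMassPosterior())
  expect_equal(p0$speech$mean, 0.5)
  expect_equal(p0$speaker$mean, 0.5)
  expect_equal(p0$difference$mean, 0)
  # planted truth reproduces the closed-form group rates
  pp <- taskHitRates(pointMassPosterior(alpha = 1.153, betaS = 0.768))
  expect_equal(pp$speech$mean, invLogit(1.153 + 0.768), tolerance = 1e-12)
  expect_equal(pp$speaker$mean, invLogit(1.153), tolerance = 1e-12)
  expect_equal(round(pp$difference$mean, 3), 0.112)
  # change-type averaging
  pv <- taskHitRates(pointMassPosterior(alpha = 0, betaS = 0, betaV = 2))
  expect_equal(pv$speaker$mean, (invLogit(0) + invLogit(2)) / 2)
  # marginal variant shrinks extreme probabilities toward 1/2
  pm <- pointMassPosterior(alpha = 2)
  pm@draws[, "sd_participant_alpha"] <- 1
  expect_lt(taskHitRates(pm, method = "marginal")$speech$mean,
            taskHitRates(pm, method = "population")$speech$mean)
})

test_that("odds ratio of a hit-rate range behaves like odds", {
  expect_equal(hitRateRangeOdds(0.5, 0.5), 1)
  expect_lt(abs(hitRateRangeOdds(0.852, 0.939) - 2.674), 1e-3)
  expect_equal(hitRateRangeOdds(0.3, 0.6) * hitRateRangeOdds(0.6, 0.9),
               hitRateRangeOdds(0.3, 0.9), tolerance = 1e-12)
  expect_error(hitRateRangeOdds(0, 0.5))
  expect_error(hitRateRangeOdds(0.9, 0.5))
})

test_that("hit model fits small data and flags degeneracies", {
  tr <- smallTrials(seed = 21)
  post <- quickHitFit(tr, seed = 2)
  s <- posteriorSummary(post)
  expect_true(all(c("alpha", "betaS", "corr_participant_12",
                    "sd_run_betaSV") %in% s$parameter))
  expect_true(all(s$hpd_low <= s$hpd_high))
  expect_true(validObject(post))
  # zero-information data: posterior slopes concentrate near 0
  tr0 <- simulateTrials(behaviorSimConfig(
    alpha = 0, betaS = 0, betaV = 0, betaSV = 0,
    sdParticipant = rep(0, 4), sdRun = rep(0, 4),
    nParticipants = 12, seed = 3))
  p0 <- quickHitFit(tr0, seed = 4, draws = 1000, warmup = 400)
  s0 <- posteriorSummary(p0)
  betas <- s0[s0$parameter %in% c("betaS", "betaV", "betaSV"), ]
  expect_true(all(abs(betas$mean) < 0.15))
  expect_true(all(betas$hpd_low < 0 & betas$hpd_high > 0))
  # separation warning on all-hit data
  trSep <- transform(smallTrials(seed = 5, nParticipants = 2), outcome = 1)
  w <- capture_warnings(fitHitModel(trSep, chains = 1, draws = 300,
                                    warmup = 100, seed = 1))
  expect_true(any(grepl("separation", w)))
})

test_that("retain keeps only the last draws per chain", {
  tr <- smallTrials(seed = 31, nParticipants = 4)
  p <- suppressWarnings(fitHitModel(tr, chains = 2, draws = 500, warmup = 200,
                                    retain = 100, seed = 6))
  expect_equal(nrow(posteriorDraws(p)), 200)
  expect_equal(as.vector(table(p@chain)), c(100, 100))
})

test_that("reaction-time model recovers a planted task effect", {
  tr <- simulateTrials(behaviorSimConfig(nParticipants = 12, nRuns = 2,
                                         rtTaskEffectMs = -50, seed = 41))
  post <- suppressWarnings(fitRtModel(tr, chains = 2, draws = 900,
                                      warmup = 350, seed = 7))
  d <- rtTaskDifference(post)
  expect_equal(d$mean, -50, tolerance = 15)
  expect_true(d$hpd[1] < -50 + 30 && d$hpd[2] > -50 - 30)
  s <- posteriorSummary(post)
  expect_true(all(c("sigma_res", "nu") %in% s$parameter))
  # identical task RTs: difference straddles zero
  tr2 <- simulateTrials(behaviorSimConfig(nParticipants = 10, nRuns = 2,
                                          rtTaskEffectMs = 0, seed = 42))
  p2 <- suppressWarnings(fitRtModel(tr2, chains = 2, draws = 700,
                                    warmup = 300, seed = 8))
  d2 <- rtTaskDifference(p2)
  expect_true(d2$hpd[1] < 0 && d2$hpd[2] > 0)
})

test_that("posterior contraction: wider data shrink the HPD", {
  trSmall <- simulateTrials(behaviorSimConfig(nParticipants = 4, seed = 51))
  trBig <- simulateTrials(behaviorSimConfig(nParticipants = 24, seed = 51))
  pS <- quickHitFit(trSmall, seed = 9, draws = 700, warmup = 300)
  pB <- quickHitFit(trBig, seed = 9, draws = 700, warmup = 300)
  wS <- subset(posteriorSummary(pS), parameter == "alpha")
  wB <- subset(posteriorSummary(pB), parameter == "alpha")
  expect_lt(wB$hpd_high - wB$hpd_low, wS$hpd_high - wS$hpd_low)
})

test_that("split-Rhat separates stationary from drifting chains", {
  set.seed(10)
  good <- rnorm(2000)
  expect_lt(splitRhat(good, rep(1:2, each = 1000)), 1.05)
  drift <- c(rnorm(1000), rnorm(1000, 3))
  expect_gt(splitRhat(drift, rep(1:2, each = 1000)), 1.5)
})

test_that("per-participant hit rates aggregate by task", {
  tr <- smallTrials(seed = 61)
  h <- participantHitRates(tr)
  expect_equal(nrow(h), 6)
  i1speech <- tr$outcome[tr$participant == 1 & tr$task == 1]
  expect_equal(h$speech[1], mean(i1speech))
})
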