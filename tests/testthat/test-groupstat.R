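test_that("RFX correlation equals the Pearson slope test", {
  set.seed(1)
  x <- rnorm(20)
  Y <- cbind(0.5 * x + rnorm(20), rnorm(20), -x + rnorm(20, sd = 0.2))
  res <- rfxCorrelation(Y, x)
  expect_equal(res$df, 18)
  for (v in 1:3) {
    ct <- cor.test(x, Y[, v])
    expect_equal(res$t[v], unname(ct$statistic), tolerance = 1e-10)
    expect_equal(res$r[v], unname(ct$estimate), tolerance = 1e-12)
  }
  # t_to_r and the slope t are mutually consistent
  expect_equal(tToR(res$t, res$df), res$r, tolerance = 1e-10)
  expect_error(rfxCorrelation(Y, rep(1, 20)), "constant covariate")
  expect_error(rfxCorrelation(Y[1:2, ], x[1:2]), "at least 3")
  expect_warning(sat <- rfxCorrelation(cbind(2 * x), x), "saturated")
  expect_true(is.infinite(sat$t[1]))
})

test_that("t-to-r transform matches its closed form and round-trips", {
  expect_equal(tToR(0, 10), 0)
  expect_lt(abs(tToR(2.97, 32) - 0.465), 5e-4)
  expect_lt(abs(tToR(2.97, 31) - 0.471), 5e-4)
  expect_equal(tToR(-3, 15), -tToR(3, 15))
  r <- 0.37; df <- 21
  t <- r * sqrt(df / (1 - r^2))
  expect_equal(tToR(t, df), r, tolerance = 1e-12)
  expect_error(tToR(1, 0), "positive")
})

test_that("pearson wraps the product-moment test", {
  x <- c(1, 2, 4, 4.5, 7)
  expect_equal(pearson(x, x)$r, 1)
  expect_error(pearson(x, rep(2, 5)), "zero variance")
  expect_error(pearson(1:2, 1:2), "at least 3")
  set.seed(2)
  ps <- replicate(800, pearson(rnorm(10), rnorm(10))$p)
  expect_gt(ks.test(ps, "punif")$p.value, 0.001)
})

test_that("permutation SVC is exact where enumeration is possible", {
  set.seed(3)
  vals <- matrix(rnorm(5 * 4), 5)
  res <- svcFwe(vals, NULL, nPermutations = 100, seed = 1)
  expect_true(res@exhaustive)
  expect_equal(res@nPermutations, 32L)
  # brute-force sign-flip oracle per voxel
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), 5)))
  for (v in 1:4) {
    tf <- function(x) mean(x) / sqrt(var(x) / 5)
    tn <- apply(signs, 1, function(s) tf(vals[, v] * s))
    expect_equal(res@pUncorrected[v],
                 mean(abs(tn) >= abs(tf(vals[, v])) - 1e-12))
  }
  # sampled permutation p agrees with the exhaustive one
  res2 <- svcFwe(vals, NULL, nPermutations = 4000, seed = 2)
  expect_true(res2@exhaustive)  # 32 <= 4000 still enumerates
  expect_equal(res2@pUncorrected, res@pUncorrected)
  # single-voxel mask: corrected equals uncorrected
  one <- svcFwe(vals[, 1, drop = FALSE], NULL, nPermutations = 100, seed = 1)
  expect_equal(one@pCorrected, one@pUncorrected)
})

test_that("SVC reports a peak inside the mask and respects seeds", {
  set.seed(4)
  vals <- matrix(rnorm(12 * 6), 12)
  vals[, 3] <- vals[, 3] + 1.2
  w <- matrix(rnorm(18), 6, 3)
  r1 <- svcFwe(vals, NULL, nPermutations = 500, seed = 9, worldCoords = w)
  r2 <- svcFwe(vals, NULL, nPermutations = 500, seed = 9, worldCoords = w)
  expect_identical(r1@pCorrected, r2@pCorrected)
  expect_equal(r1@peak$index, which.max(abs(r1@t)))
  expect_equal(r1@peak$world, w[r1@peak$index, ])
  expect_true(all(r1@pCorrected >= r1@pUncorrected - 1e-12))
})

test_that("permutation p values are valid under the null", {
  set.seed(5)
  ps <- replicate(400, {
    svcFwe(matrix(rnorm(10), 10, 1), rnorm(10), nPermutations = 99,
           seed = sample.int(1e6, 1))@pUncorrected
  })
  for (a in c(0.05, 0.1, 0.25))
    expect_lte(mean(ps <= a), a + 1 / 100 + 3 * sqrt(a * (1 - a) / 400))
})

test_that("correlation comparison tests have the stated symmetries", {
  eq <- compareCorrelations(0.4, 0.4, 30, "independent")
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  a <- compareCorrelations(0.6, 0.2, 40, "dependent-overlapping",
                           rCommon = 0.3)
  b <- compareCorrelations(0.2, 0.6, 40, "dependent-overlapping",
                           rCommon = 0.3)
  expect_equal(a$z, -b$z)
  expect_error(compareCorrelations(0.5, 0.2, 30, "dependent-overlapping"),
               "rCommon")
  expect_error(compareCorrelations(1, 0.2, 30, "independent"), "in \\(-1, 1\\)")
  no <- compareCorrelations(0.5, 0.1, 50, "dependent-nonoverlapping",
                            rCommon = c(0.2, 0.1, 0.15, 0.25))
  expect_true(is.finite(no$z) && no$p < 1)
})

test_that("dependent-overlapping comparison matches a simulation oracle", {
  # trivariate normal with known correlations; compare the implied SD of
  # z1 - z2 against the Monte-Carlo SD over independent samples
  set.seed(6)
  n <- 60
  r12 <- 0.5; r13 <- 0.2; r23 <- 0.4
  S <- matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3)
  L <- t(chol(S))
  dz <- replicate(1500, {
    X <- t(L %*% matrix(rnorm(3 * n), 3))
    atanh(cor(X[, 1], X[, 2])) - atanh(cor(X[, 1], X[, 3]))
  })
  ref <- compareCorrelations(r12, r13, n, "dependent-overlapping",
                             rCommon = r23)
  impliedSd <- abs(atanh(r12) - atanh(r13)) / abs(ref$z)
  expect_equal(sd(dz), impliedSd, tolerance = 0.12)
})

test_that("outlier refit removes extreme contrasts in one pass", {
  set.seed(7)
  contrast <- rnorm(30)
  score <- 0.5 * contrast + rnorm(30, sd = 0.5)
  base <- pearson(contrast, score)
  clean <- outlierRefit(contrast, score)
  if (length(clean$removed) == 0) expect_equal(clean$r, base$r)
  contrast2 <- c(contrast, 40)
  score2 <- c(score, 0.1)
  out <- outlierRefit(contrast2, score2)
  expect_equal(out$removed, 31L)
  expect_equal(out$n, 30)
  # planted r = 0.46 scenario: refit stays within sampling bounds
  d <- simulateContrastBehavior(correlationSimConfig(seed = 12))
  full <- pearson(d$contrast, d$score)
  refit <- outlierRefit(d$contrast, d$score)
  expect_lt(abs(atanh(refit$r) - atanh(full$r)), 2 / sqrt(30))
  expect_error(outlierRefit(1:3, 1:3), "at least 4")
})
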