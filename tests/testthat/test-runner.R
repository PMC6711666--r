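test_that("volume and table I/O round-trip", {
  v <- volumeImage(array(rnorm(4 * 5 * 6), c(4, 5, 6)), voxelSize = 1.1)
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(v, f)
  v2 <- readVolume(f)
  expect_equal(volData(v2), volData(v), tolerance = 1e-12)
  expect_equal(volAffine(v2), volAffine(v), tolerance = 1e-5)
  # integer label maps survive bit-exactly
  lab <- volumeImage(array(sample(0:10, 120, TRUE), c(4, 5, 6)))
  writeVolume(lab, f)
  expect_true(all(volData(readVolume(f)) == volData(lab)))
  # tables round-trip including missing-column handling
  tf <- tempfile(fileext = ".tsv")
  tr <- smallTrials(seed = 1, nParticipants = 2)
  writeTable(tr, tf)
  tr2 <- readTable(tf)
  expect_equal(tr2$outcome, tr$outcome)
  expect_equal(tr2$rt_ms, tr$rt_ms, tolerance = 1e-10)
  trNoRt <- tr[, setdiff(names(tr), "rt_ms")]
  writeTable(trNoRt, tf)
  expect_false("rt_ms" %in% names(readTable(tf)))
  # 4-D volumes round-trip too
  v4 <- volumeImage(array(rnorm(2 * 3 * 4 * 5), c(2, 3, 4, 5)))
  writeVolume(v4, f)
  expect_equal(dim(volData(readVolume(f))), c(2, 3, 4, 5))
})

test_that("WAV I/O round-trips float and PCM encodings", {
  w <- simulateSound("tone", 500, 0.2, 16000)
  f <- tempfile(fileext = ".wav")
  writeWav(w, 16000, f)
  back <- readWav(f)
  expect_equal(back$rate, 16000)
  expect_equal(back$wave, as.numeric(w), tolerance = 1e-6)
  writeWav(w / max(abs(w)), 16000, f, bits = 16, format = "pcm")
  back16 <- readWav(f)
  expect_equal(back16$wave, as.numeric(w / max(abs(w))), tolerance = 1e-4)
})

test_that("pipeline writes a reproducible manifest", {
  cfgFast <- list(behavior = list(draws = 400, warmup = 150, chains = 1,
                                  nParticipants = 5, nRuns = 2),
                  tonotopy = list(nParticipants = 2),
                  group = list(nPermutations = 300))
  d1 <- file.path(tempdir(), "pipeA")
  d2 <- file.path(tempdir(), "pipeB")
  m1 <- suppressWarnings(runPipeline(d1, seed = 2, config = cfgFast,
                                     verbose = FALSE))
  m2 <- suppressWarnings(runPipeline(d2, seed = 2, config = cfgFast,
                                     verbose = FALSE))
  expect_identical(m1$md5, m2$md5)                       # bit-identical rerun
  expect_true(file.exists(file.path(d1, "manifest.tsv")))
  expect_setequal(unique(m1$stage),
                  c("behavior", "tonotopy", "localizer", "group", "meta"))
  # stage subsetting runs independently with the same per-stage seeds
  d3 <- file.path(tempdir(), "pipeC")
  m3 <- runPipeline(d3, seed = 2, stages = "meta", verbose = FALSE)
  expect_identical(m3$md5[m3$file == "meta_result.tsv"],
                   m1$md5[m1$file == "meta_result.tsv"])
})

test_that("every CLI subcommand runs end to end on generated fixtures", {
  td <- file.path(tempdir(), "cli")
  dir.create(td, showWarnings = FALSE)
  p <- function(...) file.path(td, ...)

  expect_equal(cliMain(c("help")), 0L, ignore_attr = TRUE)

  # simulate: all five targets
  cliMain(c("simulate", "behavior", "--participants", "3", "--runs", "2",
            "--seed", "2", "--out", p("tr.tsv")))
  expect_gt(nrow(readTable(p("tr.tsv"))), 100)
  cliMain(c("simulate", "tonotopy", "--seed", "2", "--out", p("coef.nii.gz"),
            "--truth", p("truth.nii.gz")))
  expect_equal(length(dim(volData(readVolume(p("coef.nii.gz"))))), 4)
  cliMain(c("simulate", "correlation", "--seed", "2", "--out", p("cb.tsv")))
  expect_equal(nrow(readTable(p("cb.tsv"))), 33)
  cliMain(c("simulate", "meta", "--seed", "2", "--out", p("st.tsv")))
  cliMain(c("simulate", "sound", "--freq", "700", "--duration", "0.2",
            "--out", p("tone.wav")))
  expect_true(file.exists(p("tone.wav")))

  # features: extraction from a WAV directory, then a design
  wavDir <- p("wavs"); dir.create(wavDir, showWarnings = FALSE)
  for (f in c(300, 1200)) {
    w <- simulateSound("tone", f, 0.3)
    writeWav(w, 16000, file.path(wavDir, sprintf("s%04d.wav", f)))
  }
  cliMain(c("features", "--wav-dir", wavDir, "--out", p("feat.tsv")))
  feats <- readTable(p("feat.tsv"))
  expect_equal(dim(feats), c(2, 11))
  writeTable(data.frame(onset = c(10, 30)), p("onsets.tsv"))
  writeTable(as.data.frame(zscoreFeatures(as.matrix(feats[, -1]))),
             p("featz.tsv"))
  cliMain(c("features", "--design", "--features", p("featz.tsv"),
            "--onsets", p("onsets.tsv"), "--volumes", "20",
            "--out", p("design.tsv")))
  expect_equal(dim(readTable(p("design.tsv"))), c(20, 10))

  # glm: t map from a small 4-D volume
  set.seed(1)
  nT <- 25
  X <- cbind(reg = rnorm(nT), intercept = 1)
  arr <- array(rnorm(8 * nT), c(2, 2, 2, nT))
  arr[1, 1, 1, ] <- arr[1, 1, 1, ] + 2 * X[, 1]
  writeVolume(volumeImage(arr), p("y.nii.gz"))
  writeTable(as.data.frame(X), p("X.tsv"))
  cliMain(c("glm", "--data", p("y.nii.gz"), "--design", p("X.tsv"),
            "--weights", "1,0", "--out", p("t.nii.gz")))
  tmap <- readVolume(p("t.nii.gz"))
  expect_equal(which.max(volData(tmap)), 1L)

  # tonotopy: labels, histogram, parcellation from the simulated coefficients
  cliMain(c("tonotopy", "--coeffs", p("coef.nii.gz"), "--out",
            p("lab.nii.gz"), "--histogram", p("h.tsv"),
            "--parcellation", p("parc.tsv")))
  expect_equal(nrow(readTable(p("h.tsv"))), 72)
  expect_equal(readTable(p("parc.tsv"))$mask, c("region1", "region2"))

  # behavior: tiny hit-model fit
  suppressWarnings(cliMain(c("behavior", "--trials", p("tr.tsv"),
                             "--model", "hit", "--chains", "1",
                             "--draws", "300", "--warmup", "120",
                             "--seed", "3", "--out", p("post.tsv"))))
  expect_true("alpha" %in% readTable(p("post.tsv"))$parameter)

  # correlate
  s <- simulateContrastBehavior(correlationSimConfig(seed = 5))
  writeTable(s, p("sample.tsv"))
  cliMain(c("correlate", "--sample", p("sample.tsv"), "--perms", "200",
            "--seed", "4", "--out", p("corr.tsv")))
  corr <- readTable(p("corr.tsv"))
  expect_true(all(c("t", "r", "p_fwe") %in% corr$quantity))

  # meta
  cliMain(c("meta", "--studies", p("st.tsv"), "--out", p("meta.tsv")))
  expect_true("pooled_d" %in% readTable(p("meta.tsv"))$quantity)

  # run: a stage subset through the CLI
  cliMain(c("run", "--out-dir", p("run"), "--seed", "5", "--stages",
            "meta", "--quiet"))
  expect_true(file.exists(p("run", "manifest.tsv")))

  expect_error(cliMain(c("nonsense")), "unknown command")
})
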