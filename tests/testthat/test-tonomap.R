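test_that("best-frequency labeling takes the argmax with documented ties", {
  co <- array(0, c(2, 1, 1, 10))
  co[1, 1, 1, ] <- c(0.1, 0.9, 0.3, rep(0, 7))
  co[2, 1, 1, ] <- c(0, 0, 0.5, 0, 0, 0, 0.5, 0, 0, 0)   # tie bins 3 and 7
  m <- bestFrequency(co)
  expect_equal(m@data[1, 1, 1], 2)
  expect_equal(m@data[2, 1, 1], 3)                        # tie -> lowest bin
  # all-NA voxels are excluded from the map
  co[2, 1, 1, ] <- NA
  m2 <- bestFrequency(co)
  expect_true(is.na(m2@data[2, 1, 1]))
  expect_false(m2@mask[2, 1, 1])
})

test_that("90-degree z rotation is a pure permutation and invertible", {
  set.seed(1)
  v <- volumeImage(array(rnorm(5 * 7 * 3), c(5, 7, 3)), voxelSize = 1.1)
  r4 <- rotateVolume90z(rotateVolume90z(v, 2), 2)
  expect_identical(volData(r4), volData(v))
  rInv <- rotateVolume90z(rotateVolume90z(v, 1), -1)
  expect_identical(volData(rInv), volData(v))
  expect_equal(volAffine(rInv), volAffine(v))
  # world coordinates are preserved under the affine update
  r1 <- rotateVolume90z(v)
  idxNew <- cbind(2, 3, 2)                     # out[i,j,k] = in[j, n1+1-i, k]
  idxOld <- cbind(3, 5 - 2 + 1, 2)
  expect_equal(voxelToWorld(volAffine(r1), idxNew),
               voxelToWorld(volAffine(v), idxOld))
})

test_that("gradient histograms point along the planted direction", {
  # integer ramp increasing along the first in-plane axis: all angles 0
  d <- c(3, 12, 12)
  lab <- array(rep(1:12, each = 3), d)
  lab[lab > 10] <- 10
  mask <- array(TRUE, d)
  m <- new("BestFrequencyMap", data = lab, affine = diag(4), mask = mask,
           nBins = 10L)
  h <- suppressWarnings(gradientHistogram(m, nSlices = 3, method = "labels"))
  expect_gt(h@counts[1], 0)
  expect_equal(sum(h@counts[-1]), 0)
  # constant label field: zero gradient everywhere, empty histogram
  mc <- new("BestFrequencyMap", data = array(5, d), affine = diag(4),
            mask = mask, nBins = 10L)
  hc <- suppressWarnings(gradientHistogram(mc, nSlices = 3,
                                           method = "labels"))
  expect_equal(sum(hc@counts), 0)
  expect_error(histogramMaxima(hc), "empty")
  # planted 130-degree ramp: participant histogram maximal in [130, 135)
  sim <- simulateTonotopyVolumes(tonotopySimConfig(gradientAngles = 130,
                                                   noiseSd = 0))
  bm <- bestFrequency(sim$coefficients[[1]], sim$mask, sim$affine)
  hp <- gradientHistogram(bm)
  expect_equal(which.max(hp@counts), 130 / 5 + 1)
})

test_that("histogram maxima handle wrap-around and separation", {
  mk <- function(counts) new("AngleHistogram", counts = counts, binWidth = 5,
                             level = "group")
  # ramp at 358 degrees: reported in the [355, 360) bin, not split
  sim <- simulateTonotopyVolumes(tonotopySimConfig(gradientAngles = 355,
                                                   noiseSd = 0))
  bm <- bestFrequency(sim$coefficients[[1]], sim$mask, sim$affine)
  expect_equal(histogramMaxima(gradientHistogram(bm), k = 1), 355)
  # two planted ramps at 130 and 300
  sim2 <- simulateTonotopyVolumes(tonotopySimConfig(noiseSd = 0))
  bm2 <- bestFrequency(sim2$coefficients[[1]], sim2$mask, sim2$affine)
  expect_setequal(histogramMaxima(gradientHistogram(bm2), k = 2),
                  c(130, 300))
  # wrap-around local maximum at bin 1 spanning the 0/360 seam
  cnt <- rep(0, 72); cnt[72] <- 3; cnt[1] <- 5; cnt[2] <- 3; cnt[30] <- 4
  expect_equal(histogramMaxima(mk(cnt), k = 2), c(0, 145))
  # min separation suppresses adjacent maxima
  cnt2 <- rep(1, 72); cnt2[10] <- 9; cnt2[12] <- 8; cnt2[50] <- 7
  expect_equal(histogramMaxima(mk(cnt2), k = 2, minSeparation = 30),
               c(45, 245))
  expect_warning(histogramMaxima(mk(c(rep(0, 71), 2)), k = 2), "only 1")
})

test_that("group averaging of histograms is the mean of counts", {
  h1 <- new("AngleHistogram", counts = c(rep(0, 70), 2, 4), binWidth = 5,
            level = "participant")
  h2 <- new("AngleHistogram", counts = c(rep(0, 70), 6, 0), binWidth = 5,
            level = "participant")
  g <- averageHistograms(list(h1, h2))
  expect_equal(g@counts[71:72], c(4, 2))
  expect_equal(g@level, "group")
})

test_that("parcellation splits at the ridge and conserves voxels", {
  sim <- simulateTonotopyVolumes(tonotopySimConfig(noiseSd = 0))
  p <- parcellate(sim$truth)
  nMask <- sum(sim$mask)
  lab <- p@labels
  expect_equal(sum(!is.na(lab)), nMask)               # conservation
  expect_equal(sum(lab == 1, na.rm = TRUE) + sum(lab == 2, na.rm = TRUE) +
                 sum(lab == 3, na.rm = TRUE), nMask)
  # volumes: count x voxel volume on the 1 mm grid
  expect_equal(p@volumes[["region1"]], sum(lab == 1, na.rm = TRUE))
  # MGB-scale masks: region volumes in the tens of mm^3
  expect_gt(p@volumes[["region1"]], 10)
  expect_lt(p@volumes[["region1"]], 120)
  # the two regions sit on opposite sides (superior axis separation)
  expect_gt(abs(p@com[1, 3] - p@com[2, 3]), 0.5)
  # ridge voxels carry each slice's maximal label
  ridgeIdx <- which(!is.na(lab) & lab == 3, arr.ind = TRUE)
  for (s in unique(ridgeIdx[, 1])) {
    sliceLabs <- sim$truth@data[s, , ][sim$mask[s, , ]]
    expect_equal(unique(sim$truth@data[ridgeIdx[ridgeIdx[, 1] == s, ,
                                                drop = FALSE]]),
                 max(sliceLabs, na.rm = TRUE))
  }
})

test_that("sphere masks count lattice points inside the radius", {
  ref <- volumeImage(array(0, c(13, 13, 13)))
  expect_equal(sum(sphereMask(c(0, 0, 0), 5, ref)), 515)
  expect_equal(sum(sphereMask(c(0, 0, 0), 0, ref)), 1)
  # brute-force lattice oracle at another radius
  r <- 3.2
  g <- expand.grid(-6:6, -6:6, -6:6)
  expect_equal(sum(sphereMask(c(0, 0, 0), r, ref)),
               sum(rowSums(g^2) <= r^2 + 1e-9))
  # reflection symmetry about the centre
  msk <- sphereMask(c(0, 0, 0), 4, ref)
  expect_identical(msk, msk[13:1, , ])
  expect_error(sphereMask(c(100, 100, 100), 2, ref), "outside")
})

test_that("threshold masks apply one-sided t thresholds inside a region", {
  set.seed(2)
  d <- c(6, 6, 6)
  tmap <- array(rnorm(prod(d)), d)
  region <- array(TRUE, d)
  expect_equal(sum(thresholdMask(tmap, p = 1, df = 20, region)), prod(d))
  expect_warning(kept0 <- thresholdMask(array(0, d), 0.05, 20, region),
                 "no voxels")
  expect_equal(sum(kept0), 0)
  # calibrated null: surviving fraction approaches p
  frac <- replicate(60, {
    tm <- array(rt(prod(d), df = 20), d)
    mean(thresholdMask(tm, 0.05, 20, region))
  })
  expect_lt(abs(mean(frac) - 0.05), 0.01)
})
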