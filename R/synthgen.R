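## Synthetic-data generators: every downstream stage can be exercised against
## known ground truth without any scanner or behavioural data.

#' Evaluate an expression under a fixed RNG seed, restoring the caller's state
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

logistic <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

#' Configuration for the behavioural trial generator
#'
#' Defines the generative counterpart of the hierarchical binomial model:
#' trial-level Bernoulli outcomes whose logit is a population linear predictor
#' (intercept, task, change-type, interaction) plus correlated participant- and
#' run-level random effects drawn from multivariate normal distributions.
#'
#' Defaults correspond to a one-back speech/speaker study: 33 participants,
#' 5 runs, 6 blocks per condition per run, 14 stimuli per block with 6 or 7
#' syllable/speaker changes (the scored target trials). The population
#' intercept and task effect (1.153 and 0.768 on the logit scale) put the two
#' task hit rates near 0.87 and 0.76.
#'
#' @param nParticipants,nRuns,blocksPerConditionPerRun,stimuliPerBlock design
#'   sizes.
#' @param changesPerBlock integer set from which the per-block number of
#'   targets is drawn uniformly (default \code{c(6, 7)}).
#' @param alpha,betaS,betaV,betaSV fixed effects on the logit scale
#'   (intercept, task, change type, interaction).
#' @param sdParticipant,sdRun 4-vectors of random-effect standard deviations.
#' @param corrParticipant,corrRun 4x4 positive-definite correlation matrices.
#' @param rtMeanMs,rtSdMs,rtTaskEffectMs reaction-time generator: normal with
#'   mean \code{rtMeanMs + rtTaskEffectMs * task}.
#' @param seed integer RNG seed.
#' @return a validated config list of class \code{BehaviorSimConfig}.
#' @export
behaviorSimConfig <- function(nParticipants = 33, nRuns = 5,
                              blocksPerConditionPerRun = 6,
                              stimuliPerBlock = 14,
                              changesPerBlock = c(6, 7),
                              alpha = 1.153, betaS = 0.768,
                              betaV = 0.2, betaSV = -0.1,
                              sdParticipant = c(0.5, 0.25, 0.25, 0.25),
                              sdRun = rep(0.1, 4),
                              corrParticipant = csCorr(4, 0.3),
                              corrRun = diag(4),
                              rtMeanMs = 600, rtSdMs = 100,
                              rtTaskEffectMs = -30,
                              seed = 1L) {
  cfg <- list(nParticipants = as.integer(nParticipants),
              nRuns = as.integer(nRuns),
              blocksPerConditionPerRun = as.integer(blocksPerConditionPerRun),
              stimuliPerBlock = as.integer(stimuliPerBlock),
              changesPerBlock = as.integer(changesPerBlock),
              alpha = alpha, betaS = betaS, betaV = betaV, betaSV = betaSV,
              sdParticipant = sdParticipant, sdRun = sdRun,
              corrParticipant = corrParticipant, corrRun = corrRun,
              rtMeanMs = rtMeanMs, rtSdMs = rtSdMs,
              rtTaskEffectMs = rtTaskEffectMs,
              seed = as.integer(seed))
  class(cfg) <- "BehaviorSimConfig"
  validateBehaviorSimConfig(cfg)
  cfg
}

#' Compound-symmetric correlation matrix
#' @param d dimension
#' @param rho common off-diagonal correlation
#' @export
csCorr <- function(d, rho) {
  m <- matrix(rho, d, d)
  diag(m) <- 1
  m
}

validateBehaviorSimConfig <- function(cfg) {
  stopifnot(cfg$nParticipants >= 1, cfg$nRuns >= 1,
            cfg$blocksPerConditionPerRun >= 1,
            all(cfg$changesPerBlock >= 1),
            all(cfg$changesPerBlock <= cfg$stimuliPerBlock - 1),
            length(cfg$sdParticipant) == 4, length(cfg$sdRun) == 4,
            all(cfg$sdParticipant >= 0), all(cfg$sdRun >= 0))
  for (nm in c("corrParticipant", "corrRun")) {
    R <- cfg[[nm]]
    if (!isSymmetric(unname(R)) || any(abs(diag(R) - 1) > 1e-10))
      stop(nm, " must be symmetric with unit diagonal")
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10)
      stop(nm, " is not positive definite (min eigenvalue ",
           signif(min(ev), 3), ")")
  }
  invisible(TRUE)
}

#' Simulate target-trial outcomes from the hierarchical logistic model
#'
#' Generates one record per target trial (change event requiring a button
#' press). The outcome is Bernoulli with
#' \code{logit p = A + B_S task + B_V change + B_SV task*change}, where each
#' coefficient is the population value plus participant- and run-level draws
#' from \code{MVN(0, diag(sd) R diag(sd))}.
#'
#' @param cfg a \code{\link{behaviorSimConfig}}.
#' @return data.frame with columns participant, run, task (1 = speech,
#'   0 = speaker), change (1 = vowel, 0 = consonant), outcome (1 hit, 0 miss),
#'   rt_ms.
#' @export
simulateTrials <- function(cfg = behaviorSimConfig()) {
  validateBehaviorSimConfig(cfg)
  withSeed(cfg$seed, {
    Lp <- diag(cfg$sdParticipant) %*% t(chol(cfg$corrParticipant))
    Lr <- diag(cfg$sdRun) %*% t(chol(cfg$corrRun))
    I <- cfg$nParticipants; J <- cfg$nRuns
    up <- Lp %*% matrix(rnorm(4 * I), 4, I)   # 4 x I participant deviations
    ur <- Lr %*% matrix(rnorm(4 * J), 4, J)   # 4 x J run deviations
    beta <- c(cfg$alpha, cfg$betaS, cfg$betaV, cfg$betaSV)
    rows <- vector("list", I * J * 4L)
    idx <- 0L
    for (i in seq_len(I)) for (j in seq_len(J)) {
      for (task in c(1L, 0L)) for (change in c(1L, 0L)) {
        x <- c(1, task, change, task * change)
        eta <- sum(x * (beta + up[, i] + ur[, j]))
        p <- logistic(eta)
        nTargets <- sum(sample(cfg$changesPerBlock,
                               cfg$blocksPerConditionPerRun, replace = TRUE))
        idx <- idx + 1L
        rows[[idx]] <- data.frame(
          participant = i, run = j, task = task, change = change,
          outcome = rbinom(nTargets, 1L, p),
          rt_ms = rnorm(nTargets, cfg$rtMeanMs + cfg$rtTaskEffectMs * task,
                        cfg$rtSdMs))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Configuration for the synthetic tonotopy generator
#'
#' Describes an MGB-like ellipsoidal nucleus with planar best-frequency
#' gradients in the sagittal plane. Two gradients (default 130 and 300
#' degrees) meet at a high-frequency ridge through the nucleus centre,
#' mirroring the low-high-low frequency layout seen in the auditory thalamus.
#' Defaults give an ellipsoid of roughly 150 mm^3 on a 1 mm grid, so the two
#' parcellated regions are MGB-scale (tens of mm^3).
#'
#' @param gridShape voxel counts per axis.
#' @param voxelSize voxel edge length in mm.
#' @param nucleusCenter world-mm centre of the ellipsoid.
#' @param nucleusRadii ellipsoid semi-axes in mm (x is the slice axis).
#' @param gradientAngles in-plane angles (degrees in [0, 360)) of increasing
#'   frequency; one value gives a single planar ramp, two give ramps meeting
#'   at a ridge.
#' @param nBins number of frequency bins (labels run 1..nBins).
#' @param slope label change per mm along the gradient; \code{NULL} (default)
#'   scales the ramp to span exactly 1..nBins over the nucleus.
#' @param noiseSd SD of additive Gaussian noise on the per-bin coefficients
#'   (tuning-curve peak is 1).
#' @param nParticipants number of independent noisy replicates.
#' @param seed integer RNG seed.
#' @export
tonotopySimConfig <- function(gridShape = c(16, 16, 16), voxelSize = 1,
                              nucleusCenter = c(0, 0, 0),
                              nucleusRadii = c(5, 2.6, 3.2),
                              gradientAngles = c(130, 300),
                              nBins = 10, slope = NULL, noiseSd = 0.3,
                              nParticipants = 1, seed = 1L) {
  stopifnot(length(gridShape) == 3, all(gridShape >= 3),
            voxelSize > 0, all(nucleusRadii > 0),
            all(gradientAngles >= 0), all(gradientAngles < 360),
            length(gradientAngles) %in% c(1, 2),
            nBins >= 2, noiseSd >= 0, nParticipants >= 1)
  cfg <- list(gridShape = as.integer(gridShape), voxelSize = voxelSize,
              nucleusCenter = nucleusCenter, nucleusRadii = nucleusRadii,
              gradientAngles = gradientAngles, nBins = as.integer(nBins),
              slope = slope, noiseSd = noiseSd,
              nParticipants = as.integer(nParticipants),
              seed = as.integer(seed))
  class(cfg) <- "TonotopySimConfig"
  cfg
}

#' Simulate per-bin coefficient volumes with a planted tonotopic gradient
#'
#' Inside the ellipsoid each voxel carries a triangular frequency tuning
#' curve (unit peak, one-bin half-width) centred on a continuous best
#' frequency that
#' increases as a planar ramp along the planted angle(s); two ramps meet at a
#' high-frequency ridge through the nucleus centre. Additive Gaussian noise of
#' \code{noiseSd} is applied everywhere; outside the ellipsoid coefficients
#' are pure noise. The ground-truth labelling (noiseless argmax) is returned
#' alongside.
#'
#' @param cfg a \code{\link{tonotopySimConfig}}.
#' @return list with elements \code{coefficients} (list of 4-D arrays, one
#'   per participant, last dimension = bins), \code{truth}
#'   (\linkS4class{BestFrequencyMap}), \code{mask} (logical array),
#'   \code{affine}, and \code{config}.
#' @export
simulateTonotopyVolumes <- function(cfg = tonotopySimConfig()) {
  d <- cfg$gridShape
  affine <- diag(c(rep(cfg$voxelSize, 3), 1))
  affine[1:3, 4] <- -cfg$voxelSize * (d - 1) / 2
  ix <- slice.index(array(0, d), 1); iy <- slice.index(array(0, d), 2)
  iz <- slice.index(array(0, d), 3)
  w <- voxelToWorld(affine, cbind(c(ix), c(iy), c(iz)))
  rel <- sweep(w, 2, cfg$nucleusCenter)
  mask <- array(rowSums(sweep(rel, 2, cfg$nucleusRadii, "/")^2) <= 1, d)
  if (!any(mask)) stop("nucleus ellipsoid contains no voxels")
  # in-plane coordinates for sagittal slices: p along axis 2, q along axis 3
  p <- rel[, 2]; q <- rel[, 3]
  th <- cfg$gradientAngles * pi / 180
  proj <- sapply(th, function(a) p * cos(a) + q * sin(a))
  m <- if (length(th) == 2) pmin(proj[, 1], proj[, 2]) else proj[, 1]
  mIn <- m[c(mask)]
  slope <- cfg$slope
  if (is.null(slope)) slope <- (cfg$nBins - 1) / (max(mIn) - min(mIn))
  fCont <- cfg$nBins + slope * (m - max(mIn))   # continuous best frequency
  if (min(fCont[c(mask)]) < 0.5 - 1e-9)
    stop("gradient too steep for grid: label range exceeds nBins (",
         signif(min(fCont[c(mask)]), 3), " < 0.5); reduce slope")
  bins <- seq_len(cfg$nBins)
  # triangular tuning of unit peak and one-bin half-width: its coefficient
  # centroid equals the continuous best frequency exactly, so gradient
  # directions of the centroid field reproduce the planted angles
  tuning <- pmax(1 - abs(outer(fCont, bins, "-")), 0)  # voxels x bins
  truthLab <- bins[max.col(tuning, ties.method = "first")]
  truthArr <- array(NA_real_, d)
  truthArr[mask] <- truthLab[c(mask)]
  cleanCoef <- tuning
  cleanCoef[!c(mask), ] <- 0
  coeffs <- withSeed(cfg$seed, lapply(seq_len(cfg$nParticipants), function(s) {
    noisy <- cleanCoef + matrix(rnorm(length(cleanCoef), 0, cfg$noiseSd),
                                nrow(cleanCoef))
    array(noisy, c(d, cfg$nBins))
  }))
  truth <- new("BestFrequencyMap", data = truthArr, affine = affine,
               mask = mask, nBins = cfg$nBins,
               coefficients = array(cleanCoef, c(d, cfg$nBins)))
  list(coefficients = coeffs, truth = truth, mask = mask, affine = affine,
       config = cfg)
}

#' Configuration for the contrast/behaviour correlation generator
#'
#' @param nParticipants number of participants (default 33).
#' @param targetR planted across-participant Pearson correlation between the
#'   task-modulation contrast and the behavioural score (default 0.46).
#' @param behaviorMean,behaviorSd moments of the proportion-correct scores.
#' @param contrastSd SD of the contrast values (arbitrary units).
#' @param seed integer RNG seed.
#' @export
correlationSimConfig <- function(nParticipants = 33, targetR = 0.46,
                                 behaviorMean = 0.872, behaviorSd = 0.03,
                                 contrastSd = 1, seed = 1L) {
  stopifnot(abs(targetR) < 1, nParticipants >= 3, behaviorSd > 0,
            contrastSd > 0)
  cfg <- list(nParticipants = as.integer(nParticipants), targetR = targetR,
              behaviorMean = behaviorMean, behaviorSd = behaviorSd,
              contrastSd = contrastSd, seed = as.integer(seed))
  class(cfg) <- "CorrelationSimConfig"
  cfg
}

#' Simulate paired per-participant contrast values and behavioural scores
#'
#' Bivariate normal with the configured marginal moments and correlation;
#' behavioural scores are clipped to the open unit interval.
#'
#' @param cfg a \code{\link{correlationSimConfig}}.
#' @return data.frame with columns participant, contrast, score.
#' @export
simulateContrastBehavior <- function(cfg = correlationSimConfig()) {
  withSeed(cfg$seed, {
    n <- cfg$nParticipants
    z1 <- rnorm(n); z2 <- rnorm(n)
    contrast <- cfg$contrastSd * z1
    score <- cfg$behaviorMean + cfg$behaviorSd *
      (cfg$targetR * z1 + sqrt(1 - cfg$targetR^2) * z2)
    eps <- 1e-6
    data.frame(participant = seq_len(n), contrast = contrast,
               score = pmin(pmax(score, eps), 1 - eps))
  })
}

#' Simulate study-level effect sizes for meta-analysis
#'
#' Each study's observed standardized effect is drawn from
#' \code{Normal(trueD, tau2 + SE_i^2)} with the standard error derived from
#' the study's sample size via \code{SE = sqrt(1/n + d^2/(2n))}.
#'
#' @param k number of studies.
#' @param trueD true pooled effect size (Cohen's d).
#' @param tau2 between-study variance (>= 0).
#' @param nPerStudy sample sizes, recycled to length \code{k}.
#' @param seed integer RNG seed.
#' @return data.frame with columns label, d, se, n.
#' @export
simulateMetaStudies <- function(k = 5, trueD = 0.85, tau2 = 0.1,
                                nPerStudy = c(16, 17, 14, 17, 33),
                                seed = 1L) {
  if (k < 1) stop("at least one study is required")
  stopifnot(tau2 >= 0)
  n <- rep_len(nPerStudy, k)
  withSeed(seed, {
    se <- sqrt(1 / n + trueD^2 / (2 * n))
    d <- rnorm(k, trueD, sqrt(tau2 + se^2))
    data.frame(label = paste0("study", seq_len(k)), d = d, se = se, n = n)
  })
}

#' Simulate a stimulus waveform
#'
#' Pure tones or octave-band noise with 10 ms linear onset/offset ramps and
#' root-mean-square normalization to 1, matching the level-equalized natural
#' stimuli used with MR-compatible headphones.
#'
#' @param kind "tone" or "noise" (octave band centred on \code{freq}).
#' @param freq frequency (tone) or band centre (noise) in Hz; must be below
#'   the Nyquist frequency.
#' @param duration duration in seconds.
#' @param rate sampling rate in Hz.
#' @param seed RNG seed (noise only).
#' @return numeric waveform with attributes \code{rate}.
#' @export
simulateSound <- function(kind = c("tone", "noise"), freq = 1000,
                          duration = 1, rate = 16000, seed = 1L) {
  kind <- match.arg(kind)
  if (freq <= 0 || freq >= rate / 2)
    stop("frequency must lie in (0, rate/2): aliasing")
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  wave <- if (kind == "tone") {
    sin(2 * pi * freq * t)
  } else {
    withSeed(seed, {
      x <- rnorm(n)
      X <- fft(x)
      fr <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * rate / n
      keep <- abs(fr) >= freq / sqrt(2) & abs(fr) <= freq * sqrt(2)
      Re(fft(X * keep, inverse = TRUE)) / n
    })
  }
  nr <- max(1L, round(0.01 * rate))
  ramp <- rep(1, n)
  ramp[seq_len(nr)] <- seq(0, 1, length.out = nr)
  ramp[n - seq_len(nr) + 1] <- seq(0, 1, length.out = nr)
  wave <- wave * ramp
  wave <- wave / sqrt(mean(wave^2))
  attr(wave, "rate") <- rate
  wave
}

#' Simulate a sparse-sampling localizer schedule
#'
#' Event timings for the clustered (sparse) acquisition: volumes of
#' \code{ta} seconds separated by silent gaps, sounds presented in the middle
#' of a gap, inter-trial jitter drawn from \code{jitterTr} repetition times.
#' A fraction of trials are 1-back repeats and a fraction are silent null
#' events (both excluded from encoding-model designs).
#'
#' @param nSounds number of sound events.
#' @param tr repetition time in seconds (default 2.8).
#' @param ta acquisition time in seconds (default 1.6).
#' @param soundDuration stimulus duration in seconds.
#' @param jitterTr allowed jitters, in TRs.
#' @param repeatRate,nullRate proportions of repeat and null trials.
#' @param seed integer RNG seed.
#' @return data.frame with onset (s), volume index, isRepeat, isNull.
#' @export
simulateLocalizerSchedule <- function(nSounds = 84, tr = 2.8, ta = 1.6,
                                      soundDuration = 1,
                                      jitterTr = c(2, 3, 4),
                                      repeatRate = 0.05, nullRate = 0.05,
                                      seed = 1L) {
  withSeed(seed, {
    jit <- sample(jitterTr, nSounds, replace = TRUE)
    vol <- cumsum(jit)                      # volume preceding each sound
    gap <- tr - ta
    onset <- (vol - 1) * tr + ta + (gap - soundDuration) / 2
    data.frame(onset = onset, volume = vol,
               isRepeat = runif(nSounds) < repeatRate,
               isNull = runif(nSounds) < nullRate)
  })
}

#' Simulate a blocked speech-experiment schedule
#'
#' Continuous acquisition at \code{tr}; each run presents the four
#' task-by-change conditions in pseudo-random block order, every block
#' preceded by a 2 s task instruction and containing \code{stimuliPerBlock}
#' stimuli each followed by 400 ms of silence.
#'
#' @param nRuns number of runs.
#' @param blocksPerCondition blocks per condition per run.
#' @param stimuliPerBlock stimuli per block.
#' @param stimDuration mean stimulus duration (s).
#' @param isi inter-stimulus silence (s).
#' @param instructionDuration instruction screen duration (s).
#' @param tr repetition time (s).
#' @param changesPerBlock integer set for per-block target counts.
#' @param seed integer RNG seed.
#' @return list with \code{blocks} (run, onset, duration, task, change) and
#'   \code{events} (run, onset, task, change, isTarget).
#' @export
simulateSpeechSchedule <- function(nRuns = 5, blocksPerCondition = 6,
                                   stimuliPerBlock = 14, stimDuration = 0.803,
                                   isi = 0.4, instructionDuration = 2,
                                   tr = 1.6, changesPerBlock = c(6, 7),
                                   seed = 1L) {
  withSeed(seed, {
    conds <- expand.grid(task = c(1L, 0L), change = c(1L, 0L))
    blocks <- list(); events <- list()
    for (r in seq_len(nRuns)) {
      order <- sample(rep(seq_len(nrow(conds)), blocksPerCondition))
      t0 <- 0
      for (b in order) {
        t0 <- t0 + instructionDuration
        stimOn <- t0 + (seq_len(stimuliPerBlock) - 1) * (stimDuration + isi)
        dur <- stimuliPerBlock * (stimDuration + isi)
        nTarget <- sample(changesPerBlock, 1)
        isTarget <- rep(FALSE, stimuliPerBlock)
        isTarget[sample(2:stimuliPerBlock, nTarget)] <- TRUE
        blocks[[length(blocks) + 1L]] <- data.frame(
          run = r, onset = t0, duration = dur,
          task = conds$task[b], change = conds$change[b])
        events[[length(events) + 1L]] <- data.frame(
          run = r, onset = stimOn, task = conds$task[b],
          change = conds$change[b], isTarget = isTarget)
        t0 <- t0 + dur
      }
    }
    list(blocks = do.call(rbind, blocks), events = do.call(rbind, events))
  })
}
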