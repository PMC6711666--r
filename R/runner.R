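## Orchestration: the end-to-end demonstration pipeline on synthetic data.

#' Run the demonstration pipeline on synthetic data
#'
#' Executes the study stages end to end against generated ground truth:
#' behavioural simulation and hierarchical model fit; tonotopy simulation,
#' best-frequency labeling, gradient histograms and ridge parcellation; a
#' sparse-sampling encoding-model GLM on simulated sounds; the group-level
#' brain-behaviour correlation with permutation SVC; and the random-effects
#' meta-analysis. Every output is written under \code{outDir} and listed in
#' a manifest with MD5 hashes and the per-stage seeds.
#'
#' The global seed fans out deterministically: stage k (in the fixed stage
#' order) uses \code{seed * 100 + k}, so a stage's outputs do not depend on
#' which other stages run.
#'
#' @param outDir output directory (created if needed).
#' @param seed global integer seed.
#' @param stages subset of c("behavior", "tonotopy", "localizer", "group",
#'   "meta").
#' @param config named list of per-stage parameter overrides (see the
#'   vignette); sizes default to a few minutes of runtime.
#' @param verbose print stage progress.
#' @return data.frame manifest (file, md5, stage, seed), invisibly written
#'   to \code{manifest.tsv}.
#' @export
runPipeline <- function(outDir = tempfile("tonothal"), seed = 1L,
                        stages = c("behavior", "tonotopy", "localizer",
                                   "group", "meta"),
                        config = list(), verbose = TRUE) {
  allStages <- c("behavior", "tonotopy", "localizer", "group", "meta")
  stages <- match.arg(stages, allStages, several.ok = TRUE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  say <- function(...) if (verbose) message(sprintf(...))
  note <- function(stage, sd, ...) {
    for (f in c(...))
      manifest[[length(manifest) + 1L]] <<- data.frame(
        file = basename(f), md5 = unname(tools::md5sum(f)), stage = stage,
        seed = sd)
  }
  cfg <- function(stage, name, default) {
    v <- config[[stage]][[name]]
    if (is.null(v)) default else v
  }
  stageSeed <- function(stage) seed * 100L + match(stage, allStages)

  if ("behavior" %in% stages) {
    sd <- stageSeed("behavior")
    say("stage behavior (seed %d)", sd)
    bc <- behaviorSimConfig(
      nParticipants = cfg("behavior", "nParticipants", 12),
      nRuns = cfg("behavior", "nRuns", 3), seed = sd)
    trials <- simulateTrials(bc)
    f1 <- file.path(outDir, "trials.tsv")
    writeTable(trials, f1)
    post <- fitHitModel(trials, chains = cfg("behavior", "chains", 2),
                        draws = cfg("behavior", "draws", 1500),
                        warmup = cfg("behavior", "warmup", 500), seed = sd)
    f2 <- file.path(outDir, "posterior_summary.tsv")
    writeTable(posteriorSummary(post), f2)
    hr <- taskHitRates(post)
    f3 <- file.path(outDir, "hit_rates.tsv")
    writeTable(data.frame(
      quantity = c("speech", "speaker", "difference"),
      mean = c(hr$speech$mean, hr$speaker$mean, hr$difference$mean),
      hpd_low = c(hr$speech$hpd[1], hr$speaker$hpd[1], hr$difference$hpd[1]),
      hpd_high = c(hr$speech$hpd[2], hr$speaker$hpd[2],
                   hr$difference$hpd[2])), f3)
    note("behavior", sd, f1, f2, f3)
  }

  if ("tonotopy" %in% stages) {
    sd <- stageSeed("tonotopy")
    say("stage tonotopy (seed %d)", sd)
    tc <- tonotopySimConfig(
      nParticipants = cfg("tonotopy", "nParticipants", 4),
      noiseSd = cfg("tonotopy", "noiseSd", 0.3), seed = sd)
    sim <- simulateTonotopyVolumes(tc)
    hists <- list()
    for (s in seq_along(sim$coefficients)) {
      m <- bestFrequency(sim$coefficients[[s]], sim$mask, sim$affine)
      hists[[s]] <- gradientHistogram(m)
      if (s == 1) {
        f1 <- file.path(outDir, "best_frequency.nii.gz")
        writeVolume(new("VolumeImage",
                        data = ifelse(is.na(m@data), 0, m@data),
                        affine = m@affine), f1)
      }
    }
    grp <- averageHistograms(hists)
    f2 <- file.path(outDir, "gradient_histogram.tsv")
    writeTable(data.frame(
      bin_lower_deg = (seq_along(grp@counts) - 1) * grp@binWidth,
      count = grp@counts), f2)
    maxima <- histogramMaxima(grp)
    parc <- parcellate(sim$truth)
    f3 <- file.path(outDir, "parcellation.tsv")
    writeTable(data.frame(
      mask = c("region1", "region2"),
      com_x = parc@com[, 1], com_y = parc@com[, 2], com_z = parc@com[, 3],
      volume_mm3 = parc@volumes[1:2]), f3)
    f4 <- file.path(outDir, "gradient_maxima.tsv")
    writeTable(data.frame(maximum = seq_along(maxima),
                          angle_deg = maxima), f4)
    note("tonotopy", sd, f1, f2, f3, f4)
  }

  if ("localizer" %in% stages) {
    sd <- stageSeed("localizer")
    say("stage localizer (seed %d)", sd)
    nSounds <- cfg("localizer", "nSounds", 24)
    freqs <- withSeed(sd, 10^runif(nSounds, log10(200), log10(3500)))
    feats <- t(vapply(freqs, function(f)
      octaveBins(cochleagram(simulateSound("tone", f, duration = 0.5),
                             16000)), numeric(10)))
    fz <- zscoreFeatures(feats)
    sched <- simulateLocalizerSchedule(nSounds, seed = sd)
    nVol <- max(sched$volume) + 5
    des <- buildDesign(fz, sched$onset, sparseFrameTimes(nVol))
    f1 <- file.path(outDir, "features.tsv")
    writeTable(as.data.frame(fz), f1)
    f2 <- file.path(outDir, "localizer_design.tsv")
    writeTable(as.data.frame(designMatrix(des)), f2)
    # synthetic voxel responses with a planted best bin, then recovery
    betaTrue <- diag(10)
    Y <- designMatrix(des) %*% betaTrue +
      withSeed(sd + 1L, matrix(rnorm(nVol * 10, 0,
               cfg("localizer", "noiseSd", 0.05)), nVol))
    fit <- fitGlm(Y, des)
    best <- apply(fit@coefficients[, 1:10], 1, which.max)
    f3 <- file.path(outDir, "localizer_recovery.tsv")
    writeTable(data.frame(voxel = 1:10, planted = 1:10, recovered = best),
               f3)
    note("localizer", sd, f1, f2, f3)
  }

  if ("group" %in% stages) {
    sd <- stageSeed("group")
    say("stage group (seed %d)", sd)
    gc <- correlationSimConfig(
      nParticipants = cfg("group", "nParticipants", 33),
      targetR = cfg("group", "targetR", 0.46), seed = sd)
    pairs <- simulateContrastBehavior(gc)
    f1 <- file.path(outDir, "contrast_behavior.tsv")
    writeTable(pairs, f1)
    roi <- rfxCorrelation(pairs$contrast, pairs$score)
    # small ROI: planted voxel 1 + null voxels
    nVox <- cfg("group", "nVoxels", 12)
    vals <- withSeed(sd + 1L, cbind(pairs$contrast,
      matrix(rnorm(nrow(pairs) * (nVox - 1)), nrow(pairs))))
    svc <- svcFwe(vals, pairs$score,
                  nPermutations = cfg("group", "nPermutations", 2000),
                  seed = sd)
    f2 <- file.path(outDir, "group_correlation.tsv")
    writeTable(data.frame(
      quantity = c("roi_t", "roi_r", "df", "peak_t", "peak_p_fwe"),
      value = c(roi$t, roi$r, roi$df, svc@peak$t, svc@peak$pCorrected)), f2)
    note("group", sd, f1, f2)
  }

  if ("meta" %in% stages) {
    sd <- stageSeed("meta")
    say("stage meta (seed %d)", sd)
    studies <- simulateMetaStudies(
      k = cfg("meta", "k", 5), trueD = cfg("meta", "trueD", 0.85),
      tau2 = cfg("meta", "tau2", 0.1), seed = sd)
    f1 <- file.path(outDir, "meta_studies.tsv")
    writeTable(studies, f1)
    res <- randomEffectsMl(studies)
    f2 <- file.path(outDir, "meta_result.tsv")
    writeTable(data.frame(
      quantity = c("pooled_d", "ci_low", "ci_high", "tau2", "z", "p"),
      value = c(res@estimate, res@ci, res@tau2, res@z, res@p)), f2)
    note("meta", sd, f1, f2)
  }

  man <- do.call(rbind, manifest)
  writeTable(man, file.path(outDir, "manifest.tsv"))
  invisible(man)
}
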