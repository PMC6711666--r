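# Shared fixtures, all generated in code at test time.

# small trial table for fast model fits
smallTrials <- function(seed = 1, nParticipants = 6, nRuns = 2, ...) {
  simulateTrials(behaviorSimConfig(nParticipants = nParticipants,
                                   nRuns = nRuns, seed = seed, ...))
}

# quick hit-model fit with reduced draws
quickHitFit <- function(trials, seed = 1, draws = 800, warmup = 300,
                        chains = 2) {
  suppressWarnings(fitHitModel(trials, chains = chains, draws = draws,
                               warmup = warmup, seed = seed))
}

# a PosteriorSummary with point-mass draws at given fixed effects, for
# closed-form checks of posterior transformations
pointMassPosterior <- function(alpha = 0, betaS = 0, betaV = 0, betaSV = 0,
                               n = 200) {
  nm <- c("alpha", "betaS", "betaV", "betaSV",
          paste0("sd_participant_", c("alpha", "betaS", "betaV", "betaSV")),
          paste0("sd_run_", c("alpha", "betaS", "betaV", "betaSV")),
          paste0("corr_participant_", c("12", "13", "14", "23", "24", "34")),
          paste0("corr_run_", c("12", "13", "14", "23", "24", "34")))
  draws <- matrix(0, n, length(nm), dimnames = list(NULL, nm))
  draws[, "alpha"] <- alpha
  draws[, "betaS"] <- betaS
  draws[, "betaV"] <- betaV
  draws[, "betaSV"] <- betaSV
  smry <- data.frame(parameter = nm, mean = colMeans(draws),
                     hpd_low = colMeans(draws), hpd_high = colMeans(draws),
                     rhat = 1, ess = n)
  new("PosteriorSummary", draws = draws, chain = rep(1L, n), summary = smry,
      mass = 0.97, model = "hit", settings = list())
}

invLogit <- function(x) 1 / (1 + exp(-x))
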