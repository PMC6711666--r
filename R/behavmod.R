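## Hierarchical Bayesian models of button-press accuracy and reaction time.
##
## Likelihood (hit model): outcome_t ~ Bernoulli(logit^-1(eta_t)) with
##   eta_t = A + B_S task + B_V change + B_SV task*change,
## every coefficient decomposed into population + participant + run terms;
## the 4-vectors of participant (and run) deviations are MVN(0, diag(s) R
## diag(s)) with HalfCauchy(2) scale priors and an LKJ prior on R. Fitting
## uses the package's adaptive Metropolis-within-Gibbs sampler (src/).

#' Specification of the hierarchical hit-rate model
#'
#' Priors: Normal(0, 5) on the four fixed effects, HalfCauchy(2) on the eight
#' random-effect scales, LKJ(eta) on the two 4x4 correlation matrices.
#' Sampler defaults reproduce the original analysis settings (3 chains of
#' 20,000 draws with 5,000 warm-up); tests and demonstrations use far fewer
#' draws via the arguments of \code{\link{fitHitModel}}.
#'
#' @param betaSd fixed-effect prior SD.
#' @param cauchyScale HalfCauchy scale for random-effect SDs.
#' @param lkjEta LKJ concentration (default 2).
#' @param chains,draws,warmup sampler defaults (draws = total per chain,
#'   including warmup).
#' @param mass HPD interval mass (default 0.97).
#' @export
hitModelSpec <- function(betaSd = 5, cauchyScale = 2, lkjEta = 2,
                         chains = 3, draws = 20000, warmup = 5000,
                         mass = 0.97) {
  stopifnot(betaSd > 0, cauchyScale > 0, lkjEta > 0, warmup < draws)
  structure(list(betaSd = betaSd, cauchyScale = cauchyScale, lkjEta = lkjEta,
                 chains = chains, draws = draws, warmup = warmup,
                 mass = mass, likelihood = "bernoulli"),
            class = "HitModelSpec")
}

#' Specification of the reaction-time model
#'
#' Same random-effect structure as the hit model with a Student-t likelihood
#' on mean-centred reaction times; fixed-effect priors are T(3, 0, 1) and the
#' residual degrees of freedom are estimated.
#'
#' @inheritParams hitModelSpec
#' @param betaDf,betaScale Student-t prior parameters for the fixed effects.
#' @export
rtModelSpec <- function(betaDf = 3, betaScale = 1, cauchyScale = 2,
                        lkjEta = 2, chains = 3, draws = 20000, warmup = 5000,
                        mass = 0.97) {
  structure(list(betaDf = betaDf, betaScale = betaScale,
                 cauchyScale = cauchyScale, lkjEta = lkjEta,
                 chains = chains, draws = draws, warmup = warmup,
                 mass = mass, likelihood = "student"),
            class = "RtModelSpec")
}

paramNamesHit <- function() {
  pairs <- c("12", "13", "14", "23", "24", "34")
  c("alpha", "betaS", "betaV", "betaSV",
    paste0("sd_participant_", c("alpha", "betaS", "betaV", "betaSV")),
    paste0("sd_run_", c("alpha", "betaS", "betaV", "betaSV")),
    paste0("corr_participant_", pairs), paste0("corr_run_", pairs))
}

checkTrials <- function(trials, needRt = FALSE) {
  need <- c("participant", "run", "task", "change", "outcome")
  if (needRt) need <- c(need, "rt_ms")
  missing <- setdiff(need, names(trials))
  if (length(missing))
    stop("trial table lacks column(s): ", paste(missing, collapse = ", "))
  if (!all(trials$task %in% 0:1) || !all(trials$change %in% 0:1))
    stop("task and change must be 0/1 indicators")
  if (!needRt && !all(trials$outcome %in% 0:1))
    stop("outcome must be 0 (miss) / 1 (hit)")
  trials$participant <- match(trials$participant, unique(trials$participant))
  trials$run <- match(trials$run, unique(trials$run))
  trials
}

runSampler <- function(trials, spec, outcome, chains, draws, warmup, seed,
                       retain = NULL) {
  X <- cbind(1, trials$task, trials$change, trials$task * trials$change)
  lik <- if (spec$likelihood == "bernoulli") 0L else 1L
  nm <- paramNamesHit()
  if (lik == 1L) nm <- c(nm, "sigma_res", "nu")
  drawsList <- vector("list", chains)
  for (ch in seq_len(chains)) {
    drawsList[[ch]] <- withSeed(seed + 1000L * (ch - 1L), {
      m <- .mcmcHier(X, as.numeric(outcome),
                     as.integer(trials$participant), as.integer(trials$run),
                     lik, as.integer(draws), as.integer(warmup),
                     if (lik == 0L) spec$betaSd else 0,
                     if (lik == 1L) spec$betaDf else 0,
                     if (lik == 1L) spec$betaScale else 0,
                     as.integer(lik == 1L),
                     spec$cauchyScale, spec$lkjEta)
      if (!is.null(retain) && retain < nrow(m))
        m <- m[(nrow(m) - retain + 1):nrow(m), , drop = FALSE]
      m
    })
  }
  all <- do.call(rbind, drawsList)
  colnames(all) <- nm
  chain <- rep(seq_len(chains), vapply(drawsList, nrow, integer(1)))
  list(draws = all, chain = as.integer(chain))
}

summarizeDraws <- function(draws, chain, mass) {
  stats <- lapply(colnames(draws), function(p) {
    x <- draws[, p]
    iv <- hpd(x, mass)
    data.frame(parameter = p, mean = mean(x), hpd_low = iv[1],
               hpd_high = iv[2], rhat = splitRhat(x, chain),
               ess = essBasic(x, chain))
  })
  do.call(rbind, stats)
}

#' Split-chain potential scale reduction factor
#'
#' @param x draws (all chains stacked).
#' @param chain integer chain index per draw.
#' @return split-Rhat; values near 1 indicate convergence.
#' @export
splitRhat <- function(x, chain) {
  pieces <- list()
  for (ch in unique(chain)) {
    xs <- x[chain == ch]
    h <- floor(length(xs) / 2)
    pieces <- c(pieces, list(xs[1:h], xs[(h + 1):(2 * h)]))
  }
  m <- length(pieces)
  n <- min(lengths(pieces))
  pieces <- lapply(pieces, function(p) p[1:n])
  means <- vapply(pieces, mean, numeric(1))
  vars <- vapply(pieces, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W < 1e-300) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# crude effective sample size from summed autocorrelations (per chain)
#' @noRd
essBasic <- function(x, chain) {
  tot <- 0
  for (ch in unique(chain)) {
    xs <- x[chain == ch]
    n <- length(xs)
    if (var(xs) < 1e-300) { tot <- tot + n; next }
    rho <- stats::acf(xs, lag.max = min(200, n - 1), plot = FALSE,
                      demean = TRUE)$acf[-1]
    pos <- which(rho < 0.05)
    cut <- if (length(pos)) pos[1] else length(rho)
    tot <- tot + n / (1 + 2 * sum(rho[seq_len(cut)]))
  }
  tot
}

#' Fit the hierarchical Bayesian hit-rate model
#'
#' @param trials data.frame with columns participant, run, task (1 speech /
#'   0 speaker), change (1 vowel / 0 consonant), outcome (1 hit / 0 miss):
#'   one row per target trial.
#' @param spec a \code{\link{hitModelSpec}}.
#' @param chains,draws,warmup override the spec's sampler settings.
#' @param retain keep only the last \code{retain} post-warmup draws per chain
#'   (the original analysis retained 7,500); NULL keeps all.
#' @param seed integer seed; chains use seed, seed + 1000, ...
#' @return a \linkS4class{PosteriorSummary}. A warning is raised when any
#'   split-Rhat exceeds 1.01 (fit flagged, not discarded) or when the data
#'   are separated (all hits or all misses).
#' @export
fitHitModel <- function(trials, spec = hitModelSpec(), chains = spec$chains,
                        draws = spec$draws, warmup = spec$warmup,
                        retain = NULL, seed = 1L) {
  trials <- checkTrials(trials)
  if (length(unique(trials$participant)) < 2)
    warning("single participant: random-effect scales are prior-dominated")
  if (all(trials$outcome == 1) || all(trials$outcome == 0))
    warning("complete separation: posterior is prior-dominated")
  fit <- runSampler(trials, spec, trials$outcome, chains, draws, warmup,
                    seed, retain)
  smry <- summarizeDraws(fit$draws, fit$chain, spec$mass)
  conv <- all(smry$rhat < 1.01, na.rm = TRUE)
  if (!conv)
    warning("convergence diagnostic breach: max split-Rhat = ",
            signif(max(smry$rhat, na.rm = TRUE), 4))
  new("PosteriorSummary", draws = fit$draws, chain = fit$chain,
      summary = smry, mass = spec$mass, model = "hit",
      settings = list(chains = chains, draws = draws, warmup = warmup,
                      retain = retain, seed = seed, converged = conv))
}

#' Fit the hierarchical reaction-time model
#'
#' Student-t likelihood on mean-centred reaction times with the same
#' correlated participant/run random-effect structure as the hit model.
#'
#' @inheritParams fitHitModel
#' @param spec an \code{\link{rtModelSpec}}.
#' @return a \linkS4class{PosteriorSummary} (model = "rt"); coefficients are
#'   in seconds on the mean-centred scale (input \code{rt_ms} is converted).
#' @export
fitRtModel <- function(trials, spec = rtModelSpec(), chains = spec$chains,
                       draws = spec$draws, warmup = spec$warmup,
                       retain = NULL, seed = 1L) {
  trials <- checkTrials(trials, needRt = TRUE)
  trials <- trials[is.finite(trials$rt_ms), ]
  # model in seconds: with mean-centred reaction times on that scale the
  # T(3, 0, 1) fixed-effect priors are weakly informative
  rt <- (trials$rt_ms - mean(trials$rt_ms)) / 1000
  fit <- runSampler(trials, spec, rt, chains, draws, warmup, seed, retain)
  smry <- summarizeDraws(fit$draws, fit$chain, spec$mass)
  conv <- all(smry$rhat < 1.01, na.rm = TRUE)
  if (!conv)
    warning("convergence diagnostic breach: max split-Rhat = ",
            signif(max(smry$rhat, na.rm = TRUE), 4))
  new("PosteriorSummary", draws = fit$draws, chain = fit$chain,
      summary = smry, mass = spec$mass, model = "rt",
      settings = list(chains = chains, draws = draws, warmup = warmup,
                      retain = retain, seed = seed, converged = conv,
                      rtMean = mean(trials$rt_ms)))
}

#' Highest posterior density interval
#'
#' Narrowest contiguous interval containing the requested posterior mass
#' (sorted-sample sweep). For clearly multimodal draws the narrowest
#' contiguous interval is still returned, with attribute
#' \code{multimodal = TRUE}.
#'
#' @param draws numeric draws (>= 100 unless \code{strict = FALSE}).
#' @param mass interval mass (default 0.97).
#' @param strict enforce the minimum draw count.
#' @return c(lower, upper).
#' @export
hpd <- function(draws, mass = 0.97, strict = TRUE) {
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (strict && n < 100) stop("at least 100 draws are required")
  if (n == 1) return(c(draws, draws))
  x <- sort(draws)
  m <- max(1L, ceiling(mass * n))
  if (m >= n) return(c(x[1], x[n]))
  widths <- x[(m):n] - x[1:(n - m + 1)]
  i <- which.min(widths)
  iv <- c(x[i], x[i + m - 1])
  # multimodality note: an interior gap spanning a sizable share of the range
  gaps <- diff(x)
  rng <- x[n] - x[1]
  attr(iv, "multimodal") <- rng > 0 && max(gaps) > 0.25 * rng
  iv
}

#' Posterior task hit rates and their difference
#'
#' Per posterior draw the population-level hit probabilities are averaged
#' over the two change types:
#' \code{p_speech = (logit^-1(a + bS) + logit^-1(a + bS + bV + bSV)) / 2} and
#' \code{p_speaker = (logit^-1(a) + logit^-1(a + bV)) / 2}, with random
#' effects at zero (\code{method = "population"}). \code{method = "marginal"}
#' instead integrates each probability over the participant and run
#' random-effect distributions (Gauss-Hermite quadrature on the linear
#' predictor's normal mixture).
#'
#' @param post a \linkS4class{PosteriorSummary} from \code{\link{fitHitModel}}.
#' @param method "population" or "marginal".
#' @return list with speech, speaker, difference; each holding mean and the
#'   97 percent (or spec mass) HPD, plus the per-draw vectors.
#' @export
taskHitRates <- function(post, method = c("population", "marginal")) {
  method <- match.arg(method)
  d <- post@draws
  cells <- list(
    speech_vowel = c(1, 1, 1, 1), speech_consonant = c(1, 1, 0, 0),
    speaker_vowel = c(1, 0, 1, 0), speaker_consonant = c(1, 0, 0, 0))
  beta <- d[, c("alpha", "betaS", "betaV", "betaSV"), drop = FALSE]
  cellP <- lapply(cells, function(x) {
    eta <- as.numeric(beta %*% x)
    if (method == "population") return(logistic(eta))
    sp <- d[, paste0("sd_participant_", c("alpha", "betaS", "betaV",
                                          "betaSV")), drop = FALSE]
    sr <- d[, paste0("sd_run_", c("alpha", "betaS", "betaV", "betaSV")),
            drop = FALSE]
    # variance of x'u + x'v ignoring correlations between distinct
    # coefficients is x' S x; include correlations via the stored R draws
    v <- reVariance(d, x, "participant") + reVariance(d, x, "run")
    gh <- gaussHermiteProb(eta, sqrt(pmax(v, 0)))
    gh
  })
  pSpeech <- (cellP$speech_vowel + cellP$speech_consonant) / 2
  pSpeaker <- (cellP$speaker_vowel + cellP$speaker_consonant) / 2
  diff <- pSpeech - pSpeaker
  mk <- function(x) list(mean = mean(x), hpd = hpd(x, post@mass), draws = x)
  list(speech = mk(pSpeech), speaker = mk(pSpeaker), difference = mk(diff),
       method = method)
}

# variance of x' u where u ~ MVN(0, diag(s) R diag(s)), per posterior draw
#' @noRd
reVariance <- function(d, x, level) {
  s <- d[, paste0("sd_", level, "_", c("alpha", "betaS", "betaV", "betaSV")),
         drop = FALSE]
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  rn <- paste0("corr_", level, "_", c("12", "13", "14", "23", "24", "34"))
  v <- rowSums(sweep(s^2, 2, x^2, "*"))
  for (m in seq_len(nrow(pairs))) {
    i <- pairs[m, 1]; j <- pairs[m, 2]
    v <- v + 2 * x[i] * x[j] * s[, i] * s[, j] * d[, rn[m]]
  }
  v
}

# E[logit^-1(mu + s Z)] by 21-node Gauss-Hermite quadrature
#' @noRd
gaussHermiteProb <- function(mu, s) {
  gh <- gaussHermiteNodes21
  p <- numeric(length(mu))
  for (k in seq_along(gh$x))
    p <- p + gh$w[k] * logistic(mu + s * sqrt(2) * gh$x[k])
  p / sqrt(pi)
}

# nodes/weights of the 21-point Hermite rule (computed from the Jacobi
# matrix of the Hermite recurrence at load time)
#' @noRd
gaussHermiteNodes21 <- local({
  n <- 21
  J <- diag(0, n)
  for (k in seq_len(n - 1)) J[k, k + 1] <- J[k + 1, k] <- sqrt(k / 2)
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
})

#' Posterior reaction-time difference between tasks
#'
#' Speech-minus-speaker reaction-time effect averaged over change types:
#' \code{betaS + betaSV / 2} per draw, reported in milliseconds.
#'
#' @param post a \linkS4class{PosteriorSummary} from \code{\link{fitRtModel}}.
#' @return list with mean, HPD and the per-draw vector (all in ms).
#' @export
rtTaskDifference <- function(post) {
  x <- 1000 * (post@draws[, "betaS"] + post@draws[, "betaSV"] / 2)
  list(mean = mean(x), hpd = hpd(x, post@mass), draws = x)
}

#' Odds ratio spanned by a hit-rate range
#'
#' \code{[maxP/(1-maxP)] / [minP/(1-minP)]}: how much more likely a hit is at
#' the top of the observed performance range than at the bottom.
#'
#' @param minP,maxP probabilities strictly inside (0, 1) with
#'   \code{minP <= maxP}.
#' @return the odds ratio.
#' @export
hitRateRangeOdds <- function(minP, maxP) {
  if (minP <= 0 || maxP >= 1 || minP > maxP)
    stop("need 0 < minP <= maxP < 1")
  (maxP / (1 - maxP)) / (minP / (1 - minP))
}

#' Per-participant hit proportions by task
#'
#' @param trials a trial table (see \code{\link{fitHitModel}}).
#' @return data.frame with participant, speech, speaker proportions.
#' @export
participantHitRates <- function(trials) {
  trials <- checkTrials(trials)
  sp <- tapply(trials$outcome[trials$task == 1],
               trials$participant[trials$task == 1], mean)
  sk <- tapply(trials$outcome[trials$task == 0],
               trials$participant[trials$task == 0], mean)
  ids <- sort(unique(trials$participant))
  data.frame(participant = ids,
             speech = as.numeric(sp[as.character(ids)]),
             speaker = as.numeric(sk[as.character(ids)]))
}
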