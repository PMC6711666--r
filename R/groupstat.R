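## Group-level random-effects inference: brain-behaviour correlation maps,
## permutation-based small-volume FWE, correlation transforms/comparisons,
## outlier robustness.

#' Random-effects correlation of contrast values with a covariate
#'
#' Per voxel (or per ROI column), the t statistic of the regression slope of
#' the per-participant contrast values on the behavioural covariate, with an
#' intercept; df = n - 2. Equivalent to the Pearson correlation through
#' \code{\link{tToR}}.
#'
#' @param contrasts participants x voxels matrix (or a vector for a single
#'   ROI).
#' @param covariate per-participant scores (e.g. proportion correct).
#' @return list with per-voxel \code{t}, \code{r}, and \code{df}.
#' @export
rfxCorrelation <- function(contrasts, covariate) {
  contrasts <- as.matrix(contrasts)
  n <- nrow(contrasts)
  if (length(covariate) != n) stop("covariate length must match participants")
  if (anyNA(contrasts) || anyNA(covariate)) stop("missing participants")
  if (n < 3) stop("at least 3 participants are required")
  if (sd(covariate) < 1e-14) stop("constant covariate")
  r <- as.numeric(cor(covariate, contrasts))
  sat <- abs(r) >= 1 - 1e-12
  t <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  t[sat] <- sign(r[sat]) * Inf
  if (any(sat)) warning("perfectly linear relation: t saturated (infinite)")
  list(t = t, r = r, df = n - 2)
}

#' Permutation-based small-volume FWE correction
#'
#' Nonparametric family-wise-error control within a region of interest using
#' the max-statistic null distribution. For a covariate analysis the null is
#' built by permuting the covariate across participants; for a one-sample
#' contrast (covariate = NULL) by random sign-flips of the per-participant
#' values (exchangeability under a symmetric null). When the exhaustive null
#' (all n! orderings or 2^n sign patterns) is no larger than the requested
#' number of permutations it is enumerated exactly.
#'
#' Corrected p per voxel is the proportion of null max statistics at least as
#' large as the voxel's statistic (observed included); uncorrected p uses the
#' voxel's own permutation distribution.
#'
#' @param values participants x voxels matrix of in-mask contrast values.
#' @param covariate per-participant covariate, or NULL for a one-sample test.
#' @param nPermutations requested permutations (default 10000).
#' @param alternative "two.sided" (max |t|, default) or "greater" (max t).
#' @param seed RNG seed.
#' @param worldCoords optional voxels x 3 matrix of world coordinates for
#'   peak reporting.
#' @return an \linkS4class{SVCResult}.
#' @export
svcFwe <- function(values, covariate = NULL, nPermutations = 10000,
                   alternative = c("two.sided", "greater"), seed = 1L,
                   worldCoords = NULL) {
  alternative <- match.arg(alternative)
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) < 1) stop("mask is empty")
  stat <- function(vals, cov) {
    if (is.null(cov)) {
      mu <- colMeans(vals)
      se <- sqrt(apply(vals, 2, var) / n)
      mu / pmax(se, 1e-300)
    } else {
      rfxCorrelation(vals, cov)$t
    }
  }
  score <- function(t) if (alternative == "two.sided") abs(t) else t
  tObs <- stat(values, covariate)
  withSeed(seed, {
    if (is.null(covariate)) {
      exhaustive <- 2^n <= nPermutations
      signs <- if (exhaustive) {
        as.matrix(expand.grid(rep(list(c(1, -1)), n)))
      } else {
        matrix(sample(c(1, -1), n * nPermutations, replace = TRUE), n)
      }
      if (exhaustive) signs <- t(signs)
      nP <- ncol(signs)
      tNull <- vapply(seq_len(nP), function(p)
        stat(values * signs[, p], NULL), numeric(ncol(values)))
    } else {
      nFact <- suppressWarnings(factorial(n))
      exhaustive <- is.finite(nFact) && nFact <= nPermutations
      perms <- if (exhaustive) permutationsAll(n)
               else vapply(seq_len(nPermutations), function(p) sample(n),
                           integer(n))
      nP <- ncol(perms)
      tNull <- vapply(seq_len(nP), function(p)
        stat(values, covariate[perms[, p]]), numeric(ncol(values)))
    }
    tNull <- matrix(tNull, ncol = nP)
    sNull <- score(tNull)
    sObs <- score(tObs)
    if (exhaustive) {
      # observed statistic is one of the enumerated points
      maxNull <- apply(sNull, 2, max)
      pCorr <- vapply(sObs, function(s) mean(maxNull >= s - 1e-12),
                      numeric(1))
      pUnc <- vapply(seq_along(sObs), function(v)
        mean(sNull[v, ] >= sObs[v] - 1e-12), numeric(1))
    } else {
      maxNull <- apply(sNull, 2, max)
      pCorr <- vapply(sObs, function(s)
        (1 + sum(maxNull >= s - 1e-12)) / (nP + 1), numeric(1))
      pUnc <- vapply(seq_along(sObs), function(v)
        (1 + sum(sNull[v, ] >= sObs[v] - 1e-12)) / (nP + 1), numeric(1))
    }
  })
  peakIdx <- which.max(score(tObs))
  peak <- list(index = peakIdx, t = tObs[peakIdx],
               pCorrected = pCorr[peakIdx],
               world = if (!is.null(worldCoords)) worldCoords[peakIdx, ]
                       else NULL)
  new("SVCResult", t = as.numeric(tObs), pCorrected = pmax(pCorr, pUnc),
      pUncorrected = pUnc, peak = peak, nPermutations = as.integer(nP),
      exhaustive = exhaustive, seed = as.integer(seed))
}

# all permutations of 1..n as a matrix (n x n!)
#' @noRd
permutationsAll <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutationsAll(n - 1)
  out <- matrix(0L, n, n * ncol(sub))
  c0 <- 0
  for (k in seq_len(n)) {
    for (p in seq_len(ncol(sub))) {
      rest <- seq_len(n)[-k]
      out[, c0 + p] <- c(k, rest[sub[, p]])
    }
    c0 <- c0 + ncol(sub)
  }
  out
}

#' Convert a t statistic to a correlation coefficient
#'
#' \code{r = sign(t) sqrt(t^2 / (t^2 + df))}; the inverse of the slope-test
#' relation \code{t = r sqrt(df / (1 - r^2))}.
#'
#' @param t t statistic.
#' @param df degrees of freedom (> 0); the group correlation model implies
#'   n - 2.
#' @return correlation with the sign of t.
#' @export
tToR <- function(t, df) {
  if (any(df <= 0)) stop("df must be positive")
  sign(t) * sqrt(t^2 / (t^2 + df))
}

#' Pearson product-moment correlation with its two-sided test
#'
#' @param x,y numeric vectors (n >= 3, non-zero variance).
#' @return list with \code{r}, \code{p} (two-sided t test), \code{n}.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("at least 3 observations are required")
  if (sd(x) < 1e-14 || sd(y) < 1e-14) stop("zero variance input")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Compare two correlation coefficients
#'
#' Fisher-z based tests for the difference between two correlations:
#' \describe{
#'   \item{independent}{two correlations from independent samples
#'     (standard Fisher z difference; n2 defaults to n).}
#'   \item{dependent-overlapping}{both correlations share one variable and
#'     come from the same sample; \code{rCommon} is the correlation between
#'     the two non-shared variables (backtransformed-average method of
#'     Hittner, May and Silver).}
#'   \item{dependent-nonoverlapping}{same sample, no shared variable;
#'     \code{rCommon} must give the four cross-correlations
#'     (r13, r14, r23, r24) linking the two pairs.}
#' }
#'
#' @param r1,r2 the two correlations (in (-1, 1)).
#' @param n sample size (first sample).
#' @param overlap dependency structure (see above).
#' @param rCommon see the structure descriptions; required for the dependent
#'   cases.
#' @param n2 second sample size (independent case only).
#' @return list with \code{z} and two-sided \code{p}.
#' @export
compareCorrelations <- function(r1, r2, n,
                                overlap = c("dependent-overlapping",
                                            "dependent-nonoverlapping",
                                            "independent"),
                                rCommon = NULL, n2 = n) {
  overlap <- match.arg(overlap)
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("correlations must lie in (-1, 1)")
  z1 <- atanh(r1); z2 <- atanh(r2)
  if (overlap == "independent") {
    z <- (z1 - z2) / sqrt(1 / (n - 3) + 1 / (n2 - 3))
  } else {
    if (is.null(rCommon))
      stop("rCommon is required for dependent comparisons")
    if (overlap == "dependent-overlapping") {
      rm2 <- ((r1 + r2) / 2)^2
      c12 <- (rCommon * (1 - 2 * rm2) - 0.5 * rm2 *
                (1 - 2 * rm2 - rCommon^2)) / (1 - rm2)^2
      z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * c12))
    } else {
      if (length(rCommon) != 4)
        stop("dependent-nonoverlapping requires rCommon = c(r13, r14, r23, r24)")
      r13 <- rCommon[1]; r14 <- rCommon[2]
      r23 <- rCommon[3]; r24 <- rCommon[4]
      # Pearson-Filon covariance between r12 and r34, evaluated with the
      # backtransformed average of the two compared correlations
      rb <- (r1 + r2) / 2
      num <- 0.5 * rb^2 * (r13^2 + r14^2 + r23^2 + r24^2) +
        r13 * r24 + r14 * r23 -
        (rb * r13 * r14 + rb * r23 * r24 + rb * r13 * r23 + rb * r14 * r24)
      c12 <- num / (1 - rb^2)^2
      z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * c12))
    }
  }
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Refit a correlation after single-pass outlier removal
#'
#' Removes participants whose contrast value lies more than \code{kSd}
#' standard deviations from the contrast mean (one pass, no iteration) and
#' recomputes the Pearson correlation.
#'
#' @param contrast per-participant contrast values.
#' @param score per-participant behavioural scores.
#' @param kSd removal threshold in SD units (default 2).
#' @return list with \code{r}, \code{p}, \code{n}, \code{removed} (indices).
#' @export
outlierRefit <- function(contrast, score, kSd = 2) {
  if (length(contrast) < 4) stop("at least 4 participants are required")
  mu <- mean(contrast)
  s <- sd(contrast)
  removed <- which(abs(contrast - mu) > kSd * s)
  keep <- setdiff(seq_along(contrast), removed)
  if (length(keep) < 3) stop("outlier removal leaves too few participants")
  res <- pearson(contrast[keep], score[keep])
  c(res, list(removed = removed))
}
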