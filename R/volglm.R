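## First-level GLM machinery: designs for both acquisition schemes,
## voxelwise OLS estimation, and contrasts.

#' Code hit/miss response events onto volumes
#'
#' Button-press responses enter the design as 0.5 for a hit, -0.5 for a miss
#' and 0 elsewhere; when several target events fall inside one volume
#' acquisition the values within that volume are averaged.
#'
#' @param events data.frame with columns \code{onset} (s) and \code{outcome}
#'   (1 hit, 0 miss).
#' @param frameTimes volume acquisition onset times (s).
#' @return numeric vector, one value per volume.
#' @export
codeResponses <- function(events, frameTimes) {
  out <- numeric(length(frameTimes))
  if (is.null(events) || nrow(events) == 0) return(out)
  tr <- if (length(frameTimes) > 1) diff(frameTimes[1:2]) else 1
  vol <- findInterval(events$onset, c(frameTimes, max(frameTimes) + tr))
  val <- ifelse(events$outcome == 1, 0.5, -0.5)
  ok <- vol >= 1 & vol <= length(frameTimes)
  agg <- tapply(val[ok], vol[ok], mean)
  out[as.integer(names(agg))] <- agg
  out
}

#' First-level design for the continuous-acquisition speech experiment
#'
#' Five condition regressors (speech/vowel, speech/consonant, speaker/vowel,
#' speaker/consonant boxcars plus a 2 s task-instruction epoch) convolved with
#' the canonical HRF; one response regressor carrying the volume-averaged
#' hit/miss coding from \code{\link{codeResponses}}; nuisance columns appended
#' unconvolved.
#'
#' @param blocks data.frame with onset, duration, task (1 speech, 0 speaker),
#'   change (1 vowel, 0 consonant). An instruction epoch of
#'   \code{instructionDuration} s is modeled immediately before each block.
#' @param events data.frame of target events (onset, outcome), or NULL.
#' @param nuisance optional matrix of nuisance regressors (rows = volumes).
#' @param frameTimes volume onset times (s), continuous TR (1.6 s by default
#'   when derived from \code{nVolumes}).
#' @param instructionDuration instruction epoch length (s).
#' @param convolveResponse convolve the response regressor with the HRF
#'   (default TRUE); the pre-convolution coding is always recoverable via
#'   \code{\link{codeResponses}}.
#' @param dt microtime resolution (s).
#' @return a \linkS4class{DesignMatrix}.
#' @export
speechDesign <- function(blocks, events = NULL, nuisance = NULL, frameTimes,
                         instructionDuration = 2, convolveResponse = TRUE,
                         dt = 0.1) {
  stopifnot(all(c("onset", "duration", "task", "change") %in% names(blocks)))
  if (!all(blocks$task %in% c(0, 1)) || !all(blocks$change %in% c(0, 1)))
    stop("unknown condition label: task and change must be coded 0/1")
  condName <- function(task, change)
    paste0(ifelse(task == 1, "speech_", "speaker_"),
           ifelse(change == 1, "vowel", "consonant"))
  conds <- c("speech_vowel", "speech_consonant", "speaker_vowel",
             "speaker_consonant")
  cols <- list()
  for (cn in conds) {
    sel <- condName(blocks$task, blocks$change) == cn
    cols[[cn]] <- if (any(sel))
      hrfRegressor(blocks$onset[sel], 1, frameTimes, dt = dt,
                   durations = blocks$duration[sel])
    else numeric(length(frameTimes))
  }
  cols[["instruction"]] <- hrfRegressor(blocks$onset - instructionDuration,
                                        1, frameTimes, dt = dt,
                                        durations = instructionDuration)
  resp <- codeResponses(events, frameTimes)
  cols[["response"]] <- if (convolveResponse && any(resp != 0)) {
    hrfRegressor(frameTimes, resp, frameTimes, dt = dt)
  } else resp
  X <- do.call(cbind, cols)
  convolved <- c(rep(TRUE, 5), convolveResponse)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != length(frameTimes))
      stop("nuisance rows must match number of volumes")
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- sprintf("nuisance%02d", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
    convolved <- c(convolved, rep(FALSE, ncol(nuisance)))
  }
  X <- cbind(X, intercept = 1)
  convolved <- c(convolved, FALSE)
  new("DesignMatrix", matrix = X, frameTimes = as.numeric(frameTimes),
      convolved = convolved)
}

#' Acquisition midpoints of a sparse (clustered) acquisition
#'
#' @param nVolumes number of volumes.
#' @param tr repetition time (s).
#' @param ta acquisition time (s); the silent gap is \code{tr - ta}.
#' @return per-volume sampling times: acquisition window midpoints.
#' @export
sparseFrameTimes <- function(nVolumes, tr = 2.8, ta = 1.6) {
  (seq_len(nVolumes) - 1) * tr + ta / 2
}

#' First-level design for the sparse-sampling localizers
#'
#' Each sound is a unit impulse (stick function) at its true presentation time
#' within the silent gap on the microtime grid; the convolved HRF is sampled
#' at the acquisition-window midpoints, so stimulus presentation times and
#' acquisition times are modeled separately. Repeated (1-back target) sounds
#' and null events are excluded.
#'
#' @param schedule data.frame from \code{\link{simulateLocalizerSchedule}}
#'   (onset, isRepeat, isNull), or any data.frame with an \code{onset} column.
#' @param nVolumes number of acquired volumes.
#' @param tr,ta repetition and acquisition times (s).
#' @param dt microtime resolution (s).
#' @return a \linkS4class{DesignMatrix} with columns sound + intercept.
#' @export
localizerDesign <- function(schedule, nVolumes, tr = 2.8, ta = 1.6,
                            dt = 0.1) {
  onsets <- schedule$onset
  keep <- rep(TRUE, length(onsets))
  if (!is.null(schedule$isRepeat)) keep <- keep & !schedule$isRepeat
  if (!is.null(schedule$isNull)) keep <- keep & !schedule$isNull
  onsets <- onsets[keep]
  gapStart <- (floor(onsets / tr)) * tr + ta
  if (any(onsets < gapStart - 1e-9))
    warning("some onsets collide with an acquisition window")
  ft <- sparseFrameTimes(nVolumes, tr, ta)
  X <- cbind(sound = hrfRegressor(onsets, 1, ft, dt = dt), intercept = 1)
  new("DesignMatrix", matrix = X, frameTimes = ft,
      convolved = c(TRUE, FALSE))
}

#' Fit a voxelwise ordinary least squares GLM
#'
#' @param data a 4-D \linkS4class{VolumeImage} (x, y, z, time) or a plain
#'   time x voxels matrix.
#' @param design a \linkS4class{DesignMatrix} or \linkS4class{FrequencyDesign}
#'   (an intercept is appended to a FrequencyDesign automatically), or a
#'   plain matrix.
#' @param mask logical array selecting voxels (4-D input only).
#' @return a \linkS4class{GLMFit} with per-voxel coefficients, residual
#'   variance, and residual degrees of freedom (volumes minus design rank).
#' @export
fitGlm <- function(data, design, mask = NULL) {
  if (is(design, "FrequencyDesign")) {
    X <- cbind(designMatrix(design), intercept = 1)
    dm <- new("DesignMatrix", matrix = X,
              frameTimes = frameTimes(design),
              convolved = c(rep(TRUE, ncol(X) - 1), FALSE))
  } else if (is(design, "DesignMatrix")) {
    dm <- design
    X <- designMatrix(dm)
  } else {
    X <- as.matrix(design)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    dm <- new("DesignMatrix", matrix = X,
              frameTimes = as.numeric(seq_len(nrow(X))),
              convolved = rep(FALSE, ncol(X)))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  vox <- matrix(0L, 0, 3)
  dims <- integer(0)
  affine <- diag(4)
  if (is(data, "VolumeImage")) {
    arr <- data@data
    if (length(dim(arr)) != 4) stop("a 4-D volume is required")
    dims <- dim(arr)[1:3]
    affine <- data@affine
    if (is.null(mask)) mask <- array(TRUE, dims)
    vox <- which(array(mask, dims), arr.ind = TRUE)
    Y <- t(apply(vox, 1, function(v) arr[v[1], v[2], v[3], ]))
    Y <- t(Y)                                  # time x voxels
  } else {
    Y <- as.matrix(data)
  }
  if (nrow(Y) != nrow(X)) stop("data rows must match design rows")
  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta
  df <- nrow(X) - qrX$rank
  sigma2 <- colSums(res^2) / df
  new("GLMFit", coefficients = t(beta), sigma2 = as.numeric(sigma2),
      df = df, design = dm, voxels = vox, dim = as.integer(dims),
      affine = affine)
}

#' Compute a contrast and its t map from a GLM fit
#'
#' Effect = w'beta per voxel; t = effect / SE with
#' SE^2 = sigma2 * w'(X'X)^-1 w. Voxels with zero residual variance have an
#' undefined t and are masked out (NA).
#'
#' @param fit a \linkS4class{GLMFit}.
#' @param weights contrast weight vector (length = number of regressors);
#'   may be named to match design columns.
#' @return list with \code{effect}, \code{t}, \code{df} (and, for volume
#'   fits, \code{tVolume}: a \linkS4class{VolumeImage} of t values).
#' @export
contrastMap <- function(fit, weights) {
  X <- designMatrix(fit@design)
  if (!is.null(names(weights))) {
    w <- numeric(ncol(X))
    names(w) <- colnames(X)
    w[names(weights)] <- weights
  } else {
    if (length(weights) != ncol(X))
      stop("weight length must equal the number of regressors (",
           ncol(X), ")")
    w <- as.numeric(weights)
  }
  effect <- as.numeric(fit@coefficients %*% w)
  xtxinv <- chol2inv(chol(crossprod(X)))
  se2 <- fit@sigma2 * as.numeric(t(w) %*% xtxinv %*% w)
  t <- effect / sqrt(se2)
  t[se2 <= 0 | !is.finite(se2)] <- NA_real_
  out <- list(effect = effect, t = t, df = fit@df)
  if (length(fit@dim) == 3) {
    arr <- array(NA_real_, fit@dim)
    arr[fit@voxels] <- t
    out$tVolume <- new("VolumeImage", data = arr, affine = fit@affine)
    out$voxels <- fit@voxels
  }
  out
}

#' Separable Gaussian spatial smoothing
#'
#' Utility used when smoothing is requested before fitting (the study's
#' preprocessing used a 1 mm FWHM kernel); off by default for synthetic data.
#'
#' @param vol a \linkS4class{VolumeImage} or 3-D array.
#' @param fwhm full width at half maximum in mm.
#' @param voxelSize voxel size in mm (scalar or length 3).
#' @return object of the same type, smoothed.
#' @export
smoothVolume <- function(vol, fwhm = 1, voxelSize = 1) {
  arr <- if (is(vol, "VolumeImage")) vol@data else vol
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / rep_len(voxelSize, 3)
  sm <- arr
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s < 1e-8) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-r):r / s)^2)
    k <- k / sum(k)
    sm <- convolveAxis(sm, k, ax)
  }
  if (is(vol, "VolumeImage")) new("VolumeImage", data = sm,
                                  affine = vol@affine) else sm
}

# 1-D convolution along one axis with edge replication
#' @noRd
convolveAxis <- function(arr, kernel, axis) {
  d <- dim(arr)
  r <- (length(kernel) - 1) / 2
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, d[axis])
  n <- nrow(m)
  pad <- rbind(m[rep(1, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
  out <- matrix(0, n, ncol(m))
  for (k in seq_along(kernel))
    out <- out + kernel[k] * pad[(k - 1) + seq_len(n), , drop = FALSE]
  a <- array(out, d[perm])
  aperm(a, order(perm))
}
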