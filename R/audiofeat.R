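## Octave-band sound features and the HRF-convolved encoding design.

#' Cochlear-style band energies of a waveform
#'
#' Passes the waveform through a bank of 128 overlapping constant-Q bandpass
#' filters equally spaced on a log-frequency axis from 180 to 7040 Hz
#' (5.29 octaves) and averages the output over time, approximating the
#' spectral transformation of the cochlea. The filters are realized as
#' triangular weights on the log2-frequency axis applied to the Welch-averaged
#' power spectrum (energy convention: power, i.e. squared magnitude); each
#' filter's output is a weight-normalized average so a flat power spectrum
#' yields flat band energies.
#'
#' @param wave numeric waveform.
#' @param rate sampling rate in Hz; must be at least 2 x 7040 Hz so the top
#'   filter is below Nyquist.
#' @param nFilters number of bandpass filters (128).
#' @param fMin,fMax filterbank frequency range in Hz.
#' @param bandwidthOct triangular half-width in octaves (constant-Q:
#'   proportional to centre frequency on the linear axis).
#' @param windowSize,hop STFT analysis window (samples) and hop.
#' @return list of class \code{Cochleagram}: \code{centers} (Hz),
#'   \code{energy} (per-filter time-averaged power), \code{silent} flag.
#' @export
cochleagram <- function(wave, rate, nFilters = 128, fMin = 180, fMax = 7040,
                        bandwidthOct = NULL, windowSize = 4096, hop = 2048) {
  if (rate < 2 * fMax) stop("sampling rate must be >= ", 2 * fMax, " Hz")
  wave <- as.numeric(wave)
  spacing <- log2(fMax / fMin) / (nFilters - 1)
  if (is.null(bandwidthOct)) bandwidthOct <- 2 * spacing
  centers <- fMin * 2^((seq_len(nFilters) - 1) * spacing)
  if (length(wave) < windowSize) {                 # zero-pad short inputs
    wave <- c(wave, numeric(windowSize - length(wave)))
  }
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, windowSize - 1) / windowSize) # Hann
  starts <- seq(1, length(wave) - windowSize + 1, by = hop)
  frames <- vapply(starts, function(s) wave[s:(s + windowSize - 1)] * win,
                   numeric(windowSize))
  spec <- abs(mvfft(frames))^2
  nBinsPos <- floor(windowSize / 2) + 1
  psd <- rowMeans(spec[seq_len(nBinsPos), , drop = FALSE])  # time average
  freqs <- (seq_len(nBinsPos) - 1) * rate / windowSize
  lf <- log2(pmax(freqs, 1e-12))
  energy <- vapply(centers, function(fc) {
    wgt <- pmax(0, 1 - abs(lf - log2(fc)) / bandwidthOct)
    s <- sum(wgt)
    if (s == 0) 0 else sum(wgt * psd) / s
  }, numeric(1))
  silent <- all(abs(wave) < 1e-14)
  structure(list(centers = centers, energy = energy, silent = silent,
                 fMin = fMin, fMax = fMax),
            class = "Cochleagram")
}

#' Collapse filterbank energies into octave bins
#'
#' Divides the 180-7040 Hz tonotopic axis into \code{nBins} equal bandwidths
#' in octaves (bin b covers [180 * 2^((b-1) * delta), 180 * 2^(b * delta)) Hz
#' with delta = log2(7040/180)/nBins, about 0.4408 octaves) and averages the
#' filter energies whose centre frequency falls inside each bin. Only the
#' first \code{nKeep} bins are returned: bin 10's upper edge (~3.8 kHz) is the
#' highest band faithfully reproduced by MR-compatible headphones with a
#' linear response up to 4 kHz.
#'
#' @param c a \code{Cochleagram}.
#' @param nBins total number of octave bins (12).
#' @param nKeep number of low bins retained (10).
#' @return numeric vector of length \code{nKeep}, named by bin.
#' @export
octaveBins <- function(c, nBins = 12, nKeep = 10) {
  if (nKeep > nBins) stop("nKeep must not exceed nBins")
  delta <- log2(c$fMax / c$fMin) / nBins
  edges <- c$fMin * 2^(seq(0, nBins) * delta)
  bin <- findInterval(c$centers, edges, rightmost.closed = FALSE,
                      left.open = FALSE)
  bin[bin > nBins] <- nBins       # top filter sits on the closing edge
  out <- vapply(seq_len(nKeep), function(b) {
    sel <- bin == b
    if (!any(sel)) 0 else mean(c$energy[sel])
  }, numeric(1))
  names(out) <- sprintf("bin%02d", seq_len(nKeep))
  out
}

#' Octave bin edges of the tonotopic axis
#'
#' @param nBins number of equal-octave bins.
#' @param fMin,fMax axis range in Hz.
#' @return numeric vector of nBins + 1 edges in Hz.
#' @export
octaveBinEdges <- function(nBins = 12, fMin = 180, fMax = 7040) {
  fMin * 2^(seq(0, nBins) * log2(fMax / fMin) / nBins)
}

#' Z-score feature columns across sounds
#'
#' Standardizes each frequency-bin column to mean 0 and SD 1 across sounds so
#' that energy-rich low-frequency bins do not dominate the encoding model.
#' The alternative reading (normalizing each sound across its bins) is
#' available via \code{direction = "acrossBins"}.
#'
#' @param features sounds x bins numeric matrix.
#' @param direction "acrossSounds" (per-column; default) or "acrossBins"
#'   (per-row).
#' @return standardized matrix of the same shape.
#' @export
zscoreFeatures <- function(features, direction = c("acrossSounds",
                                                   "acrossBins")) {
  direction <- match.arg(direction)
  features <- as.matrix(features)
  if (nrow(features) < 2) stop("at least two sounds are required")
  zs <- function(m) {
    mu <- colMeans(m)
    s <- apply(m, 2, sd)
    zero <- s < 1e-14
    if (any(zero)) {
      warning("zero-variance column(s) set to 0: ",
              paste(which(zero), collapse = ", "))
      s[zero] <- 1
    }
    out <- sweep(sweep(m, 2, mu), 2, s, "/")
    out[, zero] <- 0
    out
  }
  if (direction == "acrossSounds") zs(features) else t(zs(t(features)))
}

#' Canonical double-gamma haemodynamic response function
#'
#' SPM-style difference of gamma densities: response peak at 6 s, undershoot
#' at 16 s, peak-to-undershoot ratio 6; normalized to unit peak.
#'
#' @param t time in seconds (vector).
#' @param peak,undershoot,ratio shape parameters.
#' @return HRF values at \code{t}.
#' @export
canonicalHrf <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  h <- dgamma(t, shape = peak, rate = 1) -
    dgamma(t, shape = undershoot, rate = 1) / ratio
  h[t < 0] <- 0
  pk <- max(dgamma(seq(0, 40, by = 0.01), shape = peak, rate = 1) -
              dgamma(seq(0, 40, by = 0.01), shape = undershoot, rate = 1) /
              ratio)
  h / pk
}

#' Convolve an impulse train with the HRF on a microtime grid
#'
#' @param onsets impulse times (s).
#' @param amplitudes impulse amplitudes (recycled).
#' @param frameTimes sampling times (s).
#' @param dt microtime resolution (s).
#' @param durations impulse durations in s (0 = stick; > 0 = boxcar).
#' @param hrfParams list passed to \code{\link{canonicalHrf}}.
#' @return regressor sampled at \code{frameTimes}.
#' @export
hrfRegressor <- function(onsets, amplitudes = 1, frameTimes, dt = 0.1,
                         durations = 0, hrfParams = list()) {
  amplitudes <- rep_len(amplitudes, length(onsets))
  durations <- rep_len(durations, length(onsets))
  tMax <- max(frameTimes) + 32
  grid <- seq(0, tMax, by = dt)
  stick <- numeric(length(grid))
  for (k in seq_along(onsets)) {
    if (durations[k] <= 0) {
      # point event: delta approximation, so a unit impulse produces the
      # unit-peak HRF regardless of the microtime resolution
      i0 <- round(onsets[k] / dt) + 1
      if (i0 >= 1 && i0 <= length(grid))
        stick[i0] <- stick[i0] + amplitudes[k] / dt
    } else {
      i0 <- round(onsets[k] / dt) + 1
      i1 <- max(i0, i0 + ceiling(durations[k] / dt) - 1)
      sel <- i0:i1
      sel <- sel[sel >= 1 & sel <= length(grid)]
      stick[sel] <- stick[sel] + amplitudes[k]
    }
  }
  hrf <- do.call(canonicalHrf, c(list(t = seq(0, 32, by = dt)), hrfParams))
  conv <- convolve(stick, rev(hrf), type = "open")[seq_along(grid)] * dt
  # linear interpolation onto the acquisition times
  stats::approx(grid, conv, xout = frameTimes, rule = 2)$y
}

#' Build the frequency-encoding design matrix
#'
#' Places each sound's 10-bin feature vector as impulse amplitudes at its
#' onset on a fine microtime grid, convolves every bin column with the
#' canonical HRF, and samples the result at the acquisition frame times
#' (which may be sparse: for clustered acquisition pass the per-volume
#' acquisition midpoints).
#'
#' @param features sounds x bins matrix (typically z-scored).
#' @param onsets per-sound onset times (s).
#' @param frameTimes acquisition sampling times (s).
#' @param dt microtime resolution (s).
#' @param hrfParams list passed to \code{\link{canonicalHrf}}.
#' @return a \linkS4class{FrequencyDesign}.
#' @export
buildDesign <- function(features, onsets, frameTimes, dt = 0.1,
                        hrfParams = list()) {
  features <- as.matrix(features)
  if (nrow(features) != length(onsets))
    stop("one onset per sound is required")
  if (any(onsets < 0) || any(onsets > max(frameTimes)))
    stop("onsets must fall within the scan duration")
  if (anyDuplicated(onsets))
    warning("overlapping identical onsets: amplitudes are summed")
  X <- vapply(seq_len(ncol(features)), function(f)
    hrfRegressor(onsets, features[, f], frameTimes, dt = dt,
                 hrfParams = hrfParams),
    numeric(length(frameTimes)))
  colnames(X) <- colnames(features)
  if (is.null(colnames(X)))
    colnames(X) <- sprintf("bin%02d", seq_len(ncol(X)))
  new("FrequencyDesign", features = features, onsets = as.numeric(onsets),
      frameTimes = as.numeric(frameTimes), matrix = X,
      hrf = c(list(dt = dt), hrfParams))
}
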