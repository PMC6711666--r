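#' @import methods
#' @importFrom stats sd var quantile rnorm runif rbinom median cor cor.test
#'   pt qt pnorm qnorm convolve dgamma optimize fft mvfft p.adjust complete.cases
#' @importFrom utils read.delim write.table head tail
#' @useDynLib tonothal, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' VolumeImage: a 3-D or 4-D scalar grid with a voxel-to-world affine
#'
#' The basic carrier for functional data, statistical maps and masks.
#' The affine is a 4x4 matrix mapping homogeneous 0-based voxel indices
#' (i, j, k, 1) to world coordinates in millimetres, following the NIfTI
#' convention.
#'
#' @slot data numeric array, 3-D or 4-D.
#' @slot affine 4x4 voxel-to-world matrix (mm).
#' @export
setClass("VolumeImage",
  representation(data = "array", affine = "matrix"),
  validity = function(object) {
    nd <- length(dim(object@data))
    if (!nd %in% c(3L, 4L)) return("data must be a 3-D or 4-D array")
    if (!all(dim(object@affine) == c(4L, 4L))) return("affine must be 4x4")
    if (abs(det(object@affine[1:3, 1:3])) < .Machine$double.eps)
      return("affine must be invertible")
    TRUE
  }
)

#' BestFrequencyMap: integer best-frequency labels inside a mask
#'
#' Each in-mask voxel carries the index (1..nBins) of the frequency bin with
#' the largest encoding-model coefficient. Out-of-mask voxels are NA. The
#' per-bin coefficient volumes the labels were derived from can be attached
#' (slot \code{coefficients}, a 4-D array with nBins volumes); when present
#' they allow gradient estimation on the continuous best-frequency centroid
#' rather than the quantized labels.
#'
#' @slot mask logical array, same grid as \code{data}.
#' @slot nBins number of frequency bins (10 for the standard octave model).
#' @slot coefficients optional 4-D array of per-bin coefficients (or 0-length).
#' @export
setClass("BestFrequencyMap",
  contains = "VolumeImage",
  representation(mask = "array", nBins = "integer", coefficients = "array"),
  prototype(coefficients = array(numeric(0), c(0L, 0L, 0L, 0L))),
  validity = function(object) {
    if (!identical(dim(object@mask), dim(object@data)[1:3]))
      return("mask shape must match data grid")
    lab <- object@data[object@mask]
    lab <- lab[!is.na(lab)]
    if (length(lab) && (any(lab < 1) || any(lab > object@nBins)))
      return(sprintf("labels must lie in 1..%d", object@nBins))
    TRUE
  }
)

#' FrequencyDesign: octave-bin sound features and their HRF-convolved design
#'
#' Holds the sounds-by-bins feature table (W = sounds x features), the sound
#' onset times, the acquisition frame times, and the HRF-convolved design
#' matrix sampled at those frame times.
#'
#' @slot features numeric matrix, sounds x bins (z-scored when built through
#'   the standard path).
#' @slot onsets sound onset times in seconds.
#' @slot frameTimes acquisition sampling times in seconds.
#' @slot matrix design matrix, frames x bins.
#' @slot hrf list of HRF parameters used for convolution.
#' @export
setClass("FrequencyDesign",
  representation(features = "matrix", onsets = "numeric",
                 frameTimes = "numeric", matrix = "matrix", hrf = "list"),
  validity = function(object) {
    if (nrow(object@features) != length(object@onsets))
      return("one onset per sound is required")
    if (nrow(object@matrix) != length(object@frameTimes))
      return("design rows must match frame times")
    if (ncol(object@matrix) != ncol(object@features))
      return("design columns must match feature bins")
    TRUE
  }
)

#' DesignMatrix: named regressors sampled at frame times
#'
#' First-level design for the speech experiment or the localizers: condition
#' regressors (HRF-convolved), the hit/miss response regressor, and unconvolved
#' nuisance columns.
#'
#' @slot matrix frames x regressors numeric matrix with column names.
#' @slot frameTimes acquisition times in seconds.
#' @slot convolved logical per column: was the column HRF-convolved.
#' @export
setClass("DesignMatrix",
  representation(matrix = "matrix", frameTimes = "numeric",
                 convolved = "logical"),
  validity = function(object) {
    if (nrow(object@matrix) != length(object@frameTimes))
      return("rows must equal number of frames")
    if (is.null(colnames(object@matrix)))
      return("regressors must be named")
    if (length(object@convolved) != ncol(object@matrix))
      return("convolved flag must match columns")
    TRUE
  }
)

#' GLMFit: per-voxel ordinary least squares fit
#'
#' @slot coefficients voxels x regressors matrix of OLS estimates.
#' @slot sigma2 per-voxel residual variance.
#' @slot df residual degrees of freedom (volumes minus design rank).
#' @slot design the \linkS4class{DesignMatrix} used.
#' @slot voxels integer matrix of 1-based voxel indices (voxels x 3), or
#'   0-row when the fit was run on a plain matrix.
#' @slot dim grid dimensions of the source volume (integer(3)), or integer(0).
#' @slot affine affine of the source volume.
#' @export
setClass("GLMFit",
  representation(coefficients = "matrix", sigma2 = "numeric", df = "numeric",
                 design = "DesignMatrix", voxels = "matrix", dim = "integer",
                 affine = "matrix"),
  validity = function(object) {
    if (length(object@sigma2) != nrow(object@coefficients))
      return("one residual variance per voxel is required")
    if (any(object@sigma2 < -1e-12, na.rm = TRUE))
      return("residual variance must be non-negative")
    TRUE
  }
)

#' AngleHistogram: circular histogram of tonotopic gradient directions
#'
#' Counts of in-plane gradient angles in fixed-width bins over [0, 360).
#' Counts may be non-integer after averaging over slices or participants.
#'
#' @slot counts numeric vector, one entry per bin.
#' @slot binWidth bin width in degrees (5 for the standard analysis).
#' @slot level aggregation level: "slice", "participant" or "group".
#' @export
setClass("AngleHistogram",
  representation(counts = "numeric", binWidth = "numeric", level = "character"),
  validity = function(object) {
    if (object@binWidth <= 0 || 360 %% object@binWidth != 0)
      return("binWidth must divide 360")
    if (length(object@counts) != 360 / object@binWidth)
      return("counts length must be 360/binWidth")
    if (any(object@counts < 0)) return("counts must be non-negative")
    TRUE
  }
)

#' GradientParcellation: ridge-split regions of a best-frequency map
#'
#' Per sagittal slice the voxels carrying the slice's maximal label form the
#' high-frequency ridge; remaining in-mask voxels are assigned to the region
#' on their side of the ridge. Centre of mass is reported in world mm and
#' volume in mm^3.
#'
#' @slot labels integer array: 1/2 for the two regions, 3 for ridge, NA outside.
#' @slot affine 4x4 voxel-to-world matrix.
#' @slot com 2x3 matrix of region centres of mass (world mm).
#' @slot volumes region volumes in mm^3 (named, includes ridge).
#' @export
setClass("GradientParcellation",
  representation(labels = "array", affine = "matrix", com = "matrix",
                 volumes = "numeric"))

#' PosteriorSummary: MCMC draws with means, HPD intervals and diagnostics
#'
#' @slot draws draws x parameters matrix (all chains stacked).
#' @slot chain integer chain index per draw.
#' @slot summary data.frame with parameter, mean, hpd_low, hpd_high, rhat, ess.
#' @slot mass posterior mass of the HPD intervals (0.97 by default).
#' @slot model "hit" or "rt".
#' @slot settings list of sampler settings (chains, draws, warmup, seed).
#' @export
setClass("PosteriorSummary",
  representation(draws = "matrix", chain = "integer", summary = "data.frame",
                 mass = "numeric", model = "character", settings = "list"),
  validity = function(object) {
    if (length(object@chain) != nrow(object@draws))
      return("one chain index per draw is required")
    s <- object@summary
    if (nrow(s) && any(s$hpd_low > s$hpd_high, na.rm = TRUE))
      return("HPD lower bounds must not exceed upper bounds")
    TRUE
  }
)

#' MetaResult: random-effects meta-analysis estimate
#'
#' @slot estimate pooled effect size.
#' @slot ci 95 percent Wald confidence interval.
#' @slot tau2 maximum-likelihood between-study variance.
#' @slot z Wald z statistic.
#' @slot p two-sided p value.
#' @slot weights normalized per-study weights.
#' @slot method "ML" or "REML".
#' @export
setClass("MetaResult",
  representation(estimate = "numeric", ci = "numeric", tau2 = "numeric",
                 z = "numeric", p = "numeric", weights = "numeric",
                 method = "character"),
  validity = function(object) {
    if (object@tau2 < 0) return("tau2 must be non-negative")
    if (length(object@ci) != 2L) return("ci must have two bounds")
    if (object@estimate < object@ci[1] - 1e-12 ||
        object@estimate > object@ci[2] + 1e-12)
      return("CI must contain the pooled estimate")
    if (abs(sum(object@weights) - 1) > 1e-8)
      return("weights must sum to 1")
    TRUE
  }
)

#' SVCResult: permutation small-volume FWE correction result
#'
#' @slot t observed per-voxel t values inside the mask.
#' @slot pCorrected FWE-corrected p per voxel (max-statistic permutation).
#' @slot pUncorrected per-voxel uncorrected permutation p.
#' @slot peak index (within mask) and world coordinate of the peak voxel.
#' @slot nPermutations number of permutations used (or enumerated).
#' @slot exhaustive TRUE when the null was enumerated exhaustively.
#' @slot seed RNG seed.
#' @export
setClass("SVCResult",
  representation(t = "numeric", pCorrected = "numeric",
                 pUncorrected = "numeric", peak = "list",
                 nPermutations = "integer", exhaustive = "logical",
                 seed = "integer"),
  validity = function(object) {
    if (length(object@pCorrected) != length(object@t))
      return("one corrected p per voxel is required")
    if (any(object@pCorrected + 1e-12 < object@pUncorrected))
      return("corrected p must be >= uncorrected p")
    TRUE
  }
)
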