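#' Accessors for the core classes
#'
#' Accessor generics: \code{volData}/\code{volAffine} for volumes,
#' \code{designMatrix}/\code{frameTimes} for designs, \code{posteriorDraws}
#' and \code{posteriorSummary} for fitted models.
#'
#' @param object an object of the documented class.
#' @return the slot content; see the class documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("volData", function(object) standardGeneric("volData"))

#' @rdname accessors
#' @export
setGeneric("volAffine", function(object) standardGeneric("volAffine"))

#' @rdname accessors
#' @export
setGeneric("designMatrix", function(object) standardGeneric("designMatrix"))

#' @rdname accessors
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))

#' @rdname accessors
#' @export
setGeneric("posteriorDraws", function(object) standardGeneric("posteriorDraws"))

#' @rdname accessors
#' @export
setGeneric("posteriorSummary", function(object) standardGeneric("posteriorSummary"))

#' @rdname accessors
#' @export
setMethod("volData", "VolumeImage", function(object) object@data)

#' @rdname accessors
#' @export
setMethod("volAffine", "VolumeImage", function(object) object@affine)

#' @rdname accessors
#' @export
setMethod("designMatrix", "DesignMatrix", function(object) object@matrix)

#' @rdname accessors
#' @export
setMethod("designMatrix", "FrequencyDesign", function(object) object@matrix)

#' @rdname accessors
#' @export
setMethod("frameTimes", "DesignMatrix", function(object) object@frameTimes)

#' @rdname accessors
#' @export
setMethod("frameTimes", "FrequencyDesign", function(object) object@frameTimes)

#' @rdname accessors
#' @export
setMethod("posteriorDraws", "PosteriorSummary", function(object) object@draws)

#' @rdname accessors
#' @export
setMethod("posteriorSummary", "PosteriorSummary", function(object) object@summary)

setMethod("show", "VolumeImage", function(object) {
  d <- dim(object@data)
  vox <- sqrt(colSums(object@affine[1:3, 1:3]^2))
  cat(sprintf("%s of dimension %s, voxel size %s mm\n", class(object),
              paste(d, collapse = " x "),
              paste(signif(vox, 3), collapse = " x ")))
})

setMethod("show", "BestFrequencyMap", function(object) {
  callNextMethod()
  cat(sprintf("  %d in-mask voxels, %d frequency bins%s\n",
              sum(object@mask), object@nBins,
              if (length(object@coefficients)) ", coefficients attached" else ""))
})

setMethod("show", "AngleHistogram", function(object) {
  cat(sprintf("AngleHistogram (%s level): %d bins of %g deg, total count %.1f\n",
              object@level, length(object@counts), object@binWidth,
              sum(object@counts)))
})

setMethod("show", "PosteriorSummary", function(object) {
  cat(sprintf("PosteriorSummary (%s model): %d draws x %d parameters, %d chains\n",
              object@model, nrow(object@draws), ncol(object@draws),
              length(unique(object@chain))))
  cat(sprintf("  %.0f%% HPD intervals; max split-Rhat %.3f\n",
              100 * object@mass, max(object@summary$rhat, na.rm = TRUE)))
  print(object@summary, digits = 3, row.names = FALSE)
})

setMethod("show", "MetaResult", function(object) {
  cat(sprintf("Random-effects meta-analysis (%s): d = %.2f [%.2f, %.2f], tau2 = %.3f, z = %.2f, p = %.3g\n",
              object@method, object@estimate, object@ci[1], object@ci[2],
              object@tau2, object@z, object@p))
})

setMethod("show", "SVCResult", function(object) {
  cat(sprintf("Permutation SVC over %d voxels, %d permutations%s\n",
              length(object@t), object@nPermutations,
              if (object@exhaustive) " (exhaustive)" else ""))
  cat(sprintf("  peak t = %.3f, corrected p = %.4f\n",
              object@peak$t, object@peak$pCorrected))
})

setMethod("show", "GradientParcellation", function(object) {
  cat("GradientParcellation\n")
  for (i in 1:2)
    cat(sprintf("  region %d: COM (%s) mm, volume %.2f mm^3\n", i,
                paste(sprintf("%.1f", object@com[i, ]), collapse = ", "),
                object@volumes[i]))
  cat(sprintf("  ridge: %.2f mm^3\n", object@volumes[3]))
})
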