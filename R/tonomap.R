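## Best-frequency labeling, gradient-angle histograms, ridge parcellation,
## and mask construction.

#' Label voxels by their best frequency
#'
#' Assigns each in-mask voxel the index of the frequency bin with the largest
#' encoding-model coefficient; ties are broken toward the lowest bin. Voxels
#' whose coefficients are all NA are excluded from the map.
#'
#' @param coefficients per-bin coefficient volumes: a 4-D array
#'   (x, y, z, bins) or a list of \linkS4class{VolumeImage}s/3-D arrays.
#' @param mask logical array; defaults to all voxels.
#' @param affine 4x4 voxel-to-world matrix (taken from the first VolumeImage
#'   when available).
#' @param keepCoefficients attach the coefficient array to the map (enables
#'   centroid-based gradient estimation); default TRUE.
#' @return a \linkS4class{BestFrequencyMap}.
#' @export
bestFrequency <- function(coefficients, mask = NULL, affine = NULL,
                          keepCoefficients = TRUE) {
  if (is.list(coefficients)) {
    if (is(coefficients[[1]], "VolumeImage")) {
      if (is.null(affine)) affine <- coefficients[[1]]@affine
      coefficients <- lapply(coefficients, volData)
    }
    coefficients <- array(unlist(coefficients),
                          c(dim(coefficients[[1]]), length(coefficients)))
  }
  d <- dim(coefficients)
  stopifnot(length(d) == 4)
  nBins <- d[4]
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  if (is.null(affine)) {
    affine <- diag(4)
    affine[1:3, 4] <- -(d[1:3] - 1) / 2
  }
  cm <- matrix(coefficients, prod(d[1:3]), nBins)
  allNa <- rowSums(!is.na(cm)) == 0
  lab <- rep(NA_real_, nrow(cm))
  ok <- c(mask) & !allNa
  if (any(ok)) {
    sub <- cm[ok, , drop = FALSE]
    sub[is.na(sub)] <- -Inf
    lab[ok] <- max.col(sub, ties.method = "first")
  }
  mask2 <- mask
  mask2[allNa] <- FALSE
  new("BestFrequencyMap", data = array(lab, d[1:3]), affine = affine,
      mask = mask2, nBins = as.integer(nBins),
      coefficients = if (keepCoefficients) coefficients
                     else array(numeric(0), c(0L, 0L, 0L, 0L)))
}

#' Rotate a volume by 90 degrees around the z axis
#'
#' A pure axis permutation (no interpolation): applying it four times, or
#' applying it and then its inverse (\code{times = -1}), restores the input
#' bit-exactly. The affine is updated so world coordinates are preserved.
#'
#' @param vol a \linkS4class{VolumeImage}.
#' @param times number of 90-degree turns (negative = inverse direction).
#' @return rotated \linkS4class{VolumeImage}.
#' @export
rotateVolume90z <- function(vol, times = 1) {
  times <- ((times %% 4) + 4) %% 4
  arr <- vol@data
  aff <- vol@affine
  for (i in seq_len(times)) {
    d <- dim(arr)
    nd <- length(d)
    perm <- c(2, 1, seq_len(nd)[-(1:2)])
    arr <- aperm(arr, perm)
    idx <- rep(list(quote(expr = )), nd)
    idx[[2]] <- d[1]:1                      # out[i,j,..] = in[j, n1-i+1, ..]
    arr <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
    M <- rbind(c(0, 1, 0, 0),
               c(-1, 0, 0, d[1] - 1),
               c(0, 0, 1, 0),
               c(0, 0, 0, 1))
    aff <- aff %*% M
  }
  initialize(vol, data = arr, affine = aff)
}

# continuous best-frequency field: coefficient-weighted bin centroid
#' @noRd
centroidField <- function(map) {
  d <- dim(map@coefficients)
  cm <- matrix(map@coefficients, prod(d[1:3]), d[4])
  cm <- pmax(cm, 0)
  tot <- rowSums(cm)
  f <- as.numeric(cm %*% seq_len(d[4])) / ifelse(tot > 0, tot, NA)
  array(f, d[1:3])
}

#' Gradient-angle histogram of a best-frequency map
#'
#' Computes, slice by slice, the in-plane direction of increasing best
#' frequency at every in-mask voxel and accumulates the angles in fixed-width
#' circular bins. The slice axis is sagittal (axis 1); in-plane axis 1 (grid
#' axis 2) points anterior (0 degrees) and in-plane axis 2 (grid axis 3)
#' points superior (90 degrees), the orientation obtained after rotating the
#' map by 90 degrees around z and reslicing. Gradients are central
#' differences (one-sided at mask borders); zero-gradient voxels are excluded
#' and counts are unweighted. Slice histograms are averaged into one
#' participant-level histogram.
#'
#' With \code{method = "centroid"} (default when coefficient volumes are
#' attached) the gradient is taken on the coefficient-weighted best-frequency
#' centroid, a monotone function of the underlying tonotopic field, which
#' avoids the direction quantization inherent to differencing integer labels;
#' \code{method = "labels"} uses the raw integer map.
#'
#' @param map a \linkS4class{BestFrequencyMap}.
#' @param nSlices number of adjacent slices to analyse (default 10); when
#'   fewer slices intersect the mask, all available are used with a warning.
#' @param binWidth histogram bin width in degrees (default 5).
#' @param sliceAxis grid axis along which slices are taken (default 1).
#' @param method "auto", "centroid" or "labels".
#' @return an \linkS4class{AngleHistogram} (participant level) with
#'   attribute \code{sliceCounts} (per-slice histogram matrix).
#' @export
gradientHistogram <- function(map, nSlices = 10, binWidth = 5, sliceAxis = 1,
                              method = c("auto", "centroid", "labels")) {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (length(map@coefficients)) "centroid" else "labels"
  field <- if (method == "centroid") {
    if (!length(map@coefficients))
      stop("centroid method requires attached coefficient volumes")
    centroidField(map)
  } else map@data
  mask <- map@mask
  d <- dim(mask)
  perm <- c(sliceAxis, setdiff(1:3, sliceAxis))
  field <- aperm(field, perm)
  mask <- aperm(mask, perm)
  nIn <- apply(mask, 1, sum)
  avail <- which(nIn > 0)
  if (length(avail) == 0) stop("mask is empty")
  if (length(avail) < nSlices) {
    warning(sprintf("only %d slices intersect the mask (requested %d)",
                    length(avail), nSlices))
    slices <- avail
  } else {
    # contiguous window with maximal mask coverage
    windows <- seq_len(max(avail) - nSlices + 1)
    windows <- windows[windows >= min(avail)]
    cov <- vapply(windows, function(s) sum(nIn[s:(s + nSlices - 1)]),
                  numeric(1))
    s0 <- windows[which.max(cov)]
    slices <- s0:(s0 + nSlices - 1)
  }
  nb <- as.integer(360 / binWidth)
  sliceCounts <- matrix(0, length(slices), nb)
  for (si in seq_along(slices)) {
    f <- field[slices[si], , ]
    m <- mask[slices[si], , ]
    g <- planeGradient(f, m)
    mag <- sqrt(g$gx^2 + g$gy^2)
    sel <- m & is.finite(mag) & mag > 1e-12
    if (!any(sel)) next
    ang <- (atan2(g$gy[sel], g$gx[sel]) * 180 / pi) %% 360
    # numerical guard: angles a hair under a bin edge belong to that edge
    bin <- floor(ang / binWidth + 1e-7) %% nb + 1
    sliceCounts[si, ] <- tabulate(bin, nb)
  }
  h <- new("AngleHistogram", counts = colMeans(sliceCounts),
           binWidth = binWidth, level = "participant")
  attr(h, "sliceCounts") <- sliceCounts
  h
}

# in-plane gradient: central differences inside the mask, one-sided at borders
#' @noRd
planeGradient <- function(f, m) {
  f[!m] <- NA
  d <- dim(f)
  shift <- function(mat, dx, dy) {
    out <- matrix(NA_real_, d[1], d[2])
    xs <- seq_len(d[1]) + dx; ys <- seq_len(d[2]) + dy
    okx <- xs >= 1 & xs <= d[1]; oky <- ys >= 1 & ys <= d[2]
    out[okx, oky] <- mat[xs[okx], ys[oky]]
    out
  }
  fxp <- shift(f, 1, 0); fxm <- shift(f, -1, 0)
  fyp <- shift(f, 0, 1); fym <- shift(f, 0, -1)
  gx <- ifelse(!is.na(fxp) & !is.na(fxm), (fxp - fxm) / 2,
        ifelse(!is.na(fxp), fxp - f, ifelse(!is.na(fxm), f - fxm, NA)))
  gy <- ifelse(!is.na(fyp) & !is.na(fym), (fyp - fym) / 2,
        ifelse(!is.na(fyp), fyp - f, ifelse(!is.na(fym), f - fym, NA)))
  list(gx = gx, gy = gy)
}

#' Average angle histograms across participants
#'
#' @param histograms list of \linkS4class{AngleHistogram}s with identical
#'   binning.
#' @return group-level \linkS4class{AngleHistogram} (mean counts).
#' @export
averageHistograms <- function(histograms) {
  stopifnot(length(histograms) >= 1)
  bw <- histograms[[1]]@binWidth
  counts <- rowMeans(vapply(histograms, function(h) {
    stopifnot(h@binWidth == bw)
    h@counts
  }, numeric(length(histograms[[1]]@counts))))
  new("AngleHistogram", counts = counts, binWidth = bw, level = "group")
}

#' Dominant gradient directions of an angle histogram
#'
#' Finds the k largest circular local maxima (wrap-around neighbours) at
#' least \code{minSeparation} degrees apart and reports their bin lower
#' edges. Runs of tied bins count as one candidate located at their first
#' bin.
#'
#' @param h an \linkS4class{AngleHistogram}.
#' @param k number of maxima requested (default 2).
#' @param minSeparation minimum circular separation in degrees (default 30).
#' @return numeric vector of bin lower edges (degrees), strongest first; a
#'   warning is issued when fewer than k local maxima exist.
#' @export
histogramMaxima <- function(h, k = 2, minSeparation = 30) {
  cnt <- h@counts
  if (sum(cnt) == 0) stop("histogram is empty")
  nb <- length(cnt)
  # plateau-aware circular local maxima: collapse tied runs, then require a
  # run's value to exceed both neighbouring runs (with wrap-around)
  r <- rle(cnt)
  nr <- length(r$values)
  starts <- cumsum(c(1, head(r$lengths, -1)))
  wrapMerged <- nr > 1 && r$values[1] == r$values[nr]
  isMax <- logical(nr)
  if (nr == 1) {
    isMax[1] <- TRUE
  } else {
    for (i in seq_len(nr)) {
      prv <- r$values[if (i == 1) nr else i - 1]
      nxt <- r$values[if (i == nr) 1 else i + 1]
      isMax[i] <- r$values[i] > prv && r$values[i] > nxt
    }
    if (wrapMerged && nr > 2) {
      m <- r$values[1] > r$values[nr - 1] && r$values[1] > r$values[2]
      isMax[1] <- m
      isMax[nr] <- FALSE
    }
  }
  if (!any(isMax)) isMax[which.max(r$values)] <- TRUE
  cand <- starts[isMax]
  cand <- cand[order(cnt[cand], decreasing = TRUE)]
  edges <- (cand - 1) * h@binWidth
  picked <- numeric(0)
  for (e in edges) {
    if (length(picked) == k) break
    sep <- abs(((e - picked + 180) %% 360) - 180)
    if (all(sep >= minSeparation)) picked <- c(picked, e)
  }
  if (length(picked) < k)
    warning(sprintf("only %d local maxima found (requested %d)",
                    length(picked), k))
  picked
}

#' Parcellate a best-frequency map at its high-frequency ridge
#'
#' Within each sagittal slice the voxels carrying the slice's maximal label
#' form the boundary (ridge); remaining in-mask voxels are assigned to the
#' region above (superior to) or below the ridge. Region centres of mass are
#' reported in world mm and volumes in mm^3 (voxel count x voxel volume).
#'
#' @param map a \linkS4class{BestFrequencyMap}.
#' @param sliceAxis slicing axis (default 1, sagittal).
#' @return a \linkS4class{GradientParcellation}; region 1 is the inferior
#'   (ventral) region, region 2 the superior (dorsal) region, label 3 the
#'   ridge.
#' @export
parcellate <- function(map, sliceAxis = 1) {
  lab <- map@data
  mask <- map@mask
  d <- dim(mask)
  out <- array(NA_real_, d)
  inPlane <- setdiff(1:3, sliceAxis)
  for (s in seq_len(d[sliceAxis])) {
    idx <- which(slice.index(mask, sliceAxis) == s & mask, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    labs <- lab[idx]
    topLab <- max(labs, na.rm = TRUE)
    ridge <- labs == topLab
    x <- idx[, inPlane[1]]                   # anterior axis (columns)
    y <- idx[, inPlane[2]]                   # superior axis (side)
    ridgeY <- tapply(y[ridge], x[ridge], mean)
    ridgeX <- as.numeric(names(ridgeY))
    side <- numeric(nrow(idx))
    for (v in which(!ridge)) {
      jx <- ridgeX[which.min(abs(ridgeX - x[v]))]  # nearest ridge column
      side[v] <- if (y[v] > ridgeY[as.character(jx)]) 2 else 1
    }
    val <- ifelse(ridge, 3, side)
    out[idx] <- val
  }
  vox <- abs(det(map@affine[1:3, 1:3]))
  com <- matrix(NA_real_, 2, 3,
                dimnames = list(c("region1", "region2"), c("x", "y", "z")))
  vols <- c(region1 = 0, region2 = 0, ridge = 0)
  for (r in 1:3) {
    idx <- which(!is.na(out) & out == r, arr.ind = TRUE)
    nm <- c("region1", "region2", "ridge")[r]
    vols[nm] <- nrow(idx) * vox
    if (r <= 2 && nrow(idx) > 0)
      com[r, ] <- colMeans(voxelToWorld(map@affine, idx))
  }
  new("GradientParcellation", labels = out, affine = map@affine,
      com = com, volumes = vols)
}

#' Spherical region-of-interest mask
#'
#' Selects the voxels whose world-coordinate centres lie within
#' \code{radius} mm of \code{center}. Radius 0 selects the single voxel
#' containing the centre.
#'
#' @param center world coordinate (mm), length 3.
#' @param radius sphere radius in mm (default 5).
#' @param reference a \linkS4class{VolumeImage} defining grid and affine.
#' @return logical mask array.
#' @export
sphereMask <- function(center, radius = 5, reference) {
  d <- dim(reference@data)[1:3]
  idx <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  w <- voxelToWorld(reference@affine, idx)
  dist2 <- rowSums(sweep(w, 2, center)^2)
  inside <- dist2 <= radius^2 + 1e-9
  if (!any(inside)) stop("sphere lies entirely outside the volume")
  array(inside, d)
}

#' Threshold a t map inside a region
#'
#' Keeps voxels whose one-sided t-derived p value falls below the threshold
#' inside the region mask. An empty result is valid and returned with a
#' warning.
#'
#' @param statMap \linkS4class{VolumeImage} (or array) of t values.
#' @param p uncorrected one-sided p threshold (default 0.05).
#' @param df degrees of freedom of the t map.
#' @param within logical region mask.
#' @return logical mask of surviving voxels.
#' @export
thresholdMask <- function(statMap, p = 0.05, df, within = NULL) {
  t <- if (is(statMap, "VolumeImage")) statMap@data else statMap
  if (is.null(within)) within <- array(TRUE, dim(t))
  stopifnot(identical(dim(within), dim(t)))
  pv <- pt(t, df, lower.tail = FALSE)
  keep <- within & !is.na(pv) & pv < p
  if (!any(keep)) warning("no voxels survive the threshold")
  keep
}
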