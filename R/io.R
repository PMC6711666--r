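#' Construct a VolumeImage
#'
#' @param data 3-D or 4-D numeric array.
#' @param affine 4x4 voxel-to-world matrix (mm). Defaults to an isotropic
#'   grid with the given voxel size centred so world (0,0,0) is the grid
#'   centre.
#' @param voxelSize voxel edge length in mm used when no affine is given.
#' @return a \linkS4class{VolumeImage}.
#' @export
volumeImage <- function(data, affine = NULL, voxelSize = 1) {
  data <- as.array(data)
  if (is.null(affine)) {
    d3 <- dim(data)[1:3]
    affine <- diag(c(rep(voxelSize, 3), 1))
    affine[1:3, 4] <- -voxelSize * (d3 - 1) / 2
  }
  new("VolumeImage", data = data, affine = affine)
}

#' World coordinates of voxel centres
#'
#' @param affine 4x4 voxel-to-world matrix.
#' @param idx integer matrix of 1-based voxel indices (n x 3).
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxelToWorld <- function(affine, idx) {
  idx <- rbind(t(as.matrix(idx)) - 1, 1)  # 0-based homogeneous
  t(affine %*% idx)[, 1:3, drop = FALSE]
}

#' Read and write volumes as NIfTI
#'
#' Lossless round trip of data grid plus affine. Integer-valued label maps are
#' written with an integer datatype so that reading restores them bit-exactly.
#'
#' @param x a \linkS4class{VolumeImage} (or plain array for \code{writeVolume},
#'   in which case an identity-spacing affine is used).
#' @param path file path, conventionally ending in \code{.nii} or
#'   \code{.nii.gz}.
#' @return \code{readVolume} returns a \linkS4class{VolumeImage};
#'   \code{writeVolume} returns \code{path} invisibly.
#' @export
writeVolume <- function(x, path) {
  if (!is(x, "VolumeImage")) x <- volumeImage(x)
  dat <- x@data
  isInt <- all(is.finite(dat)) && all(dat == round(dat)) &&
    max(abs(dat)) < .Machine$integer.max
  img <- RNifti::asNifti(if (isInt) array(as.integer(dat), dim(dat)) else dat)
  img <- RNifti::`sform<-`(img, structure(x@affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  new("VolumeImage", data = array(as.vector(img), dim(img)),
      affine = matrix(as.numeric(aff), 4, 4))
}

#' Read and write delimited tables with headers
#'
#' Tab-separated text with a header row; the standard interchange format for
#' trial tables, feature tables, histograms and summaries.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return \code{readTable} returns a data.frame.
#' @export
writeTable <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTable
#' @export
readTable <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Minimal WAV audio I/O (PCM, mono)
#'
#' Reads and writes RIFF/WAVE files with uncompressed PCM samples (16- or
#' 32-bit integer) or IEEE float (32-bit), mono. Samples are scaled to
#' [-1, 1] on read; on write, float data are stored as IEEE float so that
#' RMS-normalized stimuli (RMS 1) survive the round trip.
#'
#' @param wave numeric vector of samples.
#' @param rate sampling rate in Hz.
#' @param path file path.
#' @param bits bit depth for writing: 16 or 32 (PCM) when \code{format="pcm"}.
#' @param format "float" (default) or "pcm".
#' @return \code{readWav} returns \code{list(wave, rate)}.
#' @export
writeWav <- function(wave, rate, path, bits = 32, format = c("float", "pcm")) {
  format <- match.arg(format)
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(wave)
  if (format == "float") {
    bits <- 32L
    audioFormat <- 3L
    bytes <- n * 4L
  } else {
    if (!bits %in% c(16, 32)) stop("PCM bits must be 16 or 32")
    audioFormat <- 1L
    bytes <- n * bits / 8L
  }
  blockAlign <- as.integer(bits / 8)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(audioFormat, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")             # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * blockAlign), con, size = 4, endian = "little")
  writeBin(blockAlign, con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(bytes), con, size = 4, endian = "little")
  if (format == "float") {
    writeBin(as.numeric(wave), con, size = 4, endian = "little")
  } else {
    scale <- 2^(bits - 1) - 1
    writeBin(as.integer(round(pmax(pmin(wave, 1), -1) * scale)), con,
             size = bits / 8, endian = "little")
  }
  invisible(path)
}

#' @rdname writeWav
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found in ", path)
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audioFormat = readBin(con, integer(), size = 2, endian = "little"),
        channels = readBin(con, integer(), size = 2, endian = "little"),
        rate = readBin(con, integer(), size = 4, endian = "little"),
        byteRate = readBin(con, integer(), size = 4, endian = "little"),
        blockAlign = readBin(con, integer(), size = 2, endian = "little"),
        bits = readBin(con, integer(), size = 2, endian = "little"))
      if (size > 16) readBin(con, raw(), n = size - 16)
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk precedes fmt chunk in ", path)
      if (fmt$channels != 1L) stop("only mono WAV is supported")
      if (fmt$audioFormat == 3L) {
        wave <- readBin(con, numeric(), n = size / 4, size = 4,
                        endian = "little")
      } else if (fmt$audioFormat == 1L) {
        bytes <- fmt$bits / 8
        wave <- readBin(con, integer(), n = size / bytes, size = bytes,
                        endian = "little") / (2^(fmt$bits - 1) - 1)
      } else stop("unsupported WAV encoding: ", fmt$audioFormat)
      return(list(wave = wave, rate = fmt$rate))
    } else {
      readBin(con, raw(), n = size + size %% 2)
    }
  }
}
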