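## Slice-stack IO, HU calibration, full-stack histograms.

#' Natural (alphanumeric) sort of file names
#'
#' Orders embedded integers numerically, so \code{s2.tif} precedes
#' \code{s10.tif} -- the order scanner exports are meant to stack in.
#'
#' @param x character vector of file names.
#' @return \code{x} reordered.
#' @export
naturalSort <- function(x) {
  if (!length(x)) return(x)
  parts <- regmatches(x, gregexpr("[0-9]+|[^0-9]+", x))
  maxlen <- max(lengths(parts))
  keys <- lapply(seq_len(maxlen), function(i) {
    piece <- vapply(parts, function(p) if (i <= length(p)) p[i] else "",
                    character(1))
    num <- suppressWarnings(as.numeric(piece))
    # numeric pieces sort before text pieces of equal position
    list(ifelse(is.na(num), 1L, 0L), ifelse(is.na(num), 0, num),
         ifelse(is.na(num), piece, ""))
  })
  ord <- do.call(order, unlist(keys, recursive = FALSE))
  x[ord]
}

readSliceFile <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    img <- tiff::readTIFF(path, as.is = TRUE)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path, info = TRUE)
    depth <- attr(img, "info")$bit.depth
    if (is.null(depth)) depth <- 8L
    img <- img * (2^depth - 1)   # back to stored integer grayscale
  } else {
    stop("unsupported image format: ", basename(path))
  }
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # grayscale from channel 1
  img
}

#' Read a directory of axial slices into a CTVolume
#'
#' Files matching \code{pattern} are stacked in natural-sort order
#' (\code{s2} before \code{s10}); slice file order becomes the z axis.
#' Stored integer grayscale values are used as-is (no rescaling), since
#' HU calibration is defined on stored grayscale indices.  If the
#' directory contains a \code{metadata.json} sidecar, its
#' \code{voxel_size_um} and \code{calibrated} fields override the
#' arguments.
#'
#' @param directoryPath directory containing one image file per slice.
#' @param pattern regular expression selecting slice files.
#' @param voxelSizeUm voxel size in micrometres (default 35).
#' @param calibrated whether values are already HU.
#' @return A [CTVolume-class].
#' @export
readSliceStack <- function(directoryPath, pattern = "\\.(tiff?|png)$",
                           voxelSizeUm = 35, calibrated = FALSE) {
  files <- list.files(directoryPath, pattern = pattern, ignore.case = TRUE)
  if (!length(files)) stop("no slice files found in ", directoryPath)
  files <- naturalSort(files)
  sidecar <- file.path(directoryPath, "metadata.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (!is.null(meta$voxel_size_um)) voxelSizeUm <- meta$voxel_size_um
    if (!is.null(meta$calibrated)) calibrated <- meta$calibrated
  }
  first <- readSliceFile(file.path(directoryPath, files[1]))
  nz <- length(files)
  vox <- array(0, dim = c(nz, nrow(first), ncol(first)))
  vox[1, , ] <- first
  for (i in seq_len(nz)[-1]) {
    img <- readSliceFile(file.path(directoryPath, files[i]))
    if (!identical(dim(img), dim(first)))
      stop(sprintf("slice %d (%s) has dimensions %dx%d, expected %dx%d",
                   i, files[i], nrow(img), ncol(img),
                   nrow(first), ncol(first)))
    vox[i, , ] <- img
  }
  CTVolume(vox, voxelSizeUm = voxelSizeUm, calibrated = calibrated)
}

#' Write a CTVolume or BinaryMask as a TIFF slice stack
#'
#' Integer-valued volumes are written as 16-bit grayscale TIFF, masks as
#' 8-bit 0/255.  A \code{metadata.json} sidecar records voxel size and
#' calibration state so [readSliceStack()] round-trips exactly.
#'
#' @param x a [CTVolume-class] or [BinaryMask-class].
#' @param directoryPath output directory (created if needed).
#' @param prefix slice file prefix.
#' @return invisibly, the written file paths.
#' @export
writeSliceStack <- function(x, directoryPath, prefix = "slice") {
  dir.create(directoryPath, showWarnings = FALSE, recursive = TRUE)
  if (is(x, "BinaryMask")) {
    vox <- array(ifelse(x@mask, 255, 0), dim = dim(x@mask))
    bits <- 8L; maxval <- 255
    meta <- list(kind = "mask")
  } else {
    vox <- x@voxels
    bits <- 16L; maxval <- 65535
    if (any(vox != round(vox)) || any(vox < 0) || any(vox > maxval))
      stop("writeSliceStack requires integer grayscale values in [0, 65535]")
    meta <- list(kind = "volume", voxel_size_um = x@voxelSizeUm,
                 calibrated = x@calibrated,
                 axis_order = "zyx")
  }
  nz <- dim(vox)[1]
  paths <- file.path(directoryPath,
                     sprintf("%s%0*d.tif", prefix, nchar(nz) + 1L, seq_len(nz)))
  for (z in seq_len(nz))
    tiff::writeTIFF(vox[z, , ] / maxval, paths[z], bits.per.sample = bits)
  jsonlite::write_json(meta, file.path(directoryPath, "metadata.json"),
                       auto_unbox = TRUE)
  invisible(paths)
}

#' Apply two-point HU calibration to a raw volume
#'
#' The linear map \code{HU(g) = 1000 * (g - waterGray) / (waterGray -
#' airGray)} sends the water anchor exactly to 0 HU and the air anchor
#' exactly to -1000 HU.
#'
#' @param volume a raw (uncalibrated) [CTVolume-class].
#' @param model a [CalibrationModel-class].
#' @return A calibrated [CTVolume-class] in HU.
#' @export
calibrateToHU <- function(volume, model) {
  stopifnot(is(volume, "CTVolume"), is(model, "CalibrationModel"))
  if (volume@calibrated) stop("volume is already calibrated")
  # ratio first so both anchors map exactly (g = air gives -1 * 1000)
  hu <- (volume@voxels - model@waterGray) /
    (model@waterGray - model@airGray) * 1000
  CTVolume(hu, voxelSizeUm = volume@voxelSizeUm, calibrated = TRUE)
}

#' Full-stack HU histogram of an ROI
#'
#' Tallies ROI voxels into 1-HU-wide bins spanning -1000 to +1000 HU
#' (half-open \code{[h, h+1)}, last bin closed at +1000).  Voxels
#' outside the plotted range are counted in the underflow/overflow
#' counters rather than dropped, so the totals always conserve the ROI
#' voxel count.
#'
#' @param volume a calibrated [CTVolume-class].
#' @param roi a [BinaryMask-class] of the same shape (default: whole
#'   volume).
#' @return An [HUHistogram-class].
#' @export
stackHistogram <- function(volume, roi = NULL) {
  stopifnot(is(volume, "CTVolume"))
  if (!volume@calibrated) stop("histogram requires a calibrated volume")
  if (is.null(roi)) roi <- BinaryMask(array(TRUE, dim(volume@voxels)))
  if (!identical(dim(roi@mask), dim(volume@voxels)))
    stop("ROI shape does not match volume shape")
  hu <- volume@voxels[roi@mask]
  under <- sum(hu < -1000)
  over <- sum(hu > 1000)
  inb <- hu[hu >= -1000 & hu <= 1000]
  idx <- pmin(floor(inb) + 1001, 2000)   # last bin [999, 1000] closed
  counts <- tabulate(idx, nbins = 2000)
  new("HUHistogram", binEdges = seq(-1000, 1000), counts = as.numeric(counts),
      underflow = as.numeric(under), overflow = as.numeric(over),
      roiVoxelCount = as.numeric(length(hu)))
}

#' @describeIn stackHistogram export as a data.frame of (huBin, count),
#'   where huBin is the lower edge of each 1-HU bin.
#' @param x an HUHistogram.
#' @param row.names,optional,... ignored; for the generic.
#' @export
as.data.frame.HUHistogram <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(huBin = x@binEdges[-length(x@binEdges)], count = x@counts)
}
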