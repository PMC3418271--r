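## The automated aerated-lung segmentation algorithm.
##
## Pipeline on a calibrated volume:
##   1. thresholdAir         -- voxels at or below the air threshold
##   2. externalAirMask      -- 2D despeckle: keep only border-connected
##                              air per slice (air outside the animal)
##   3. bodyROI              -- complement = the animal (plus bed)
##   4. erodeROI             -- sharpen the ROI border (10 px square)
##   5. thresholdAir in ROI  -- all air inside the animal
##   6. largestComponent3D   -- sweep: lung is the largest 3D object
## No step is interactive; the same parameters are reused scan after scan.

#' Threshold a calibrated volume at an air density
#'
#' Marks voxels whose density is at or below \code{thresholdHU}.  The
#' boundary is included: "excluding all pixels above the threshold"
#' keeps voxels equal to it, and the same rule is applied in both
#' scanning modes.
#'
#' @param volume a calibrated [CTVolume-class].
#' @param thresholdHU air threshold in HU (-580 euthanized, -383 in
#'   vivo).
#' @return A [BinaryMask-class], TRUE where \code{HU <= thresholdHU}.
#' @export
thresholdAir <- function(volume, thresholdHU) {
  stopifnot(is(volume, "CTVolume"))
  if (!volume@calibrated)
    stop("thresholdAir requires a calibrated volume (HU)")
  BinaryMask(volume@voxels <= thresholdHU)
}

#' External-air mask: 2D despeckle of enclosed pores
#'
#' Per axial slice, keeps only the air components (8-connectivity) that
#' touch the slice border; every enclosed 2D air "pore" -- including
#' the lungs, which are always enclosed by the body in axial thorax
#' slices -- is removed.  What remains is the air outside the animal.
#'
#' @param airMask a [BinaryMask-class] from [thresholdAir()].
#' @return A [BinaryMask-class] of external air.
#' @export
externalAirMask <- function(airMask) {
  stopifnot(is(airMask, "BinaryMask"))
  d <- dim(airMask@mask)
  out <- cpp_border_air_2d(as.logical(airMask@mask), as.integer(d))
  BinaryMask(array(out, d))
}

#' Body region of interest
#'
#' The complement of the external air: the animal (including all its
#' internal air) plus any support such as the scanner bed.  The later
#' largest-component sweep isolates the lung from the rest.
#'
#' @param externalAir a [BinaryMask-class] from [externalAirMask()].
#' @return A [BinaryMask-class] ROI.
#' @export
bodyROI <- function(externalAir) {
  stopifnot(is(externalAir, "BinaryMask"))
  roi <- !externalAir@mask
  if (!any(roi)) stop("no subject in field of view")
  BinaryMask(roi)
}

#' Erode the ROI border
#'
#' Per-slice 2D erosion by a square (Chebyshev) structuring element of
#' the given radius (side \code{2r + 1}), sharpening the ROI shape and
#' discarding the partial-volume rim where skin meets external air.
#'
#' @param roi a [BinaryMask-class].
#' @param radiusPx erosion radius in pixels (default 10).
#' @return The eroded [BinaryMask-class].
#' @export
erodeROI <- function(roi, radiusPx = 10L) {
  stopifnot(is(roi, "BinaryMask"), radiusPx >= 0)
  if (!any(roi@mask)) stop("cannot erode an empty ROI")
  d <- dim(roi@mask)
  out <- cpp_erode2d_square(as.logical(roi@mask), as.integer(d),
                            as.integer(radiusPx))
  if (!any(out)) stop("ROI vanished under erosion")
  BinaryMask(array(out, d))
}

#' Keep only the largest 3D connected component (sweep)
#'
#' Components are 26-connected in 3D, so the left and right lungs --
#' joined through the trachea and main bronchi -- form one object while
#' isolated low-density pockets (e.g. air in subcutaneous fat) are
#' swept away.  Ties in size are broken deterministically in favour of
#' the component containing the lexicographically smallest (z, y, x)
#' voxel.
#'
#' @param mask a non-empty [BinaryMask-class].
#' @return A [BinaryMask-class] holding exactly one component.
#' @export
largestComponent3D <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  if (!any(mask@mask)) stop("empty segmentation")
  d <- dim(mask@mask)
  lab <- cpp_label3d_26(as.logical(mask@mask), as.integer(d))
  # labels are numbered in lexicographic (z,y,x) discovery order, so the
  # smallest label among the largest components wins the tie-break
  keep <- which.max(lab$sizes)
  BinaryMask(array(lab$labels == keep, d))
}

#' Segment the aerated lung volume
#'
#' Runs the full automated algorithm on a calibrated volume and reports
#' the aerated-lung mask together with voxel count, volume in mm^3 and
#' the full-stack HU histogram of the body ROI.
#'
#' @param volume a calibrated [CTVolume-class].
#' @param params a [SegmentationParams-class]; defaults to euthanized
#'   mode (-580 HU, 10 px erosion).
#' @return A [SegmentationResult-class].
#' @export
segmentAeratedLung <- function(volume, params = SegmentationParams()) {
  stopifnot(is(volume, "CTVolume"), is(params, "SegmentationParams"))
  air <- thresholdAir(volume, params@airThresholdHU)
  extAir <- externalAirMask(air)
  roi <- bodyROI(extAir)
  hist <- stackHistogram(volume, roi)
  eroded <- erodeROI(roi, params@erosionRadiusPx)
  innerAir <- BinaryMask(air@mask & eroded@mask)
  if (!any(innerAir@mask)) stop("empty segmentation")
  lung <- largestComponent3D(innerAir)
  nvox <- sum(lung@mask)
  mm3 <- nvox * (volume@voxelSizeUm / 1000)^3
  new("SegmentationResult", lungMask = lung, bodyROI = roi,
      erodedROI = eroded, voxelCount = as.numeric(nvox),
      volumeMm3 = mm3, histogram = hist, params = params)
}
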