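#' Construct a CTVolume
#'
#' @param voxels 3D numeric array, \code{dim = c(nz, ny, nx)}, indexed
#'   \code{[z, y, x]} (slice, row, column).
#' @param voxelSizeUm isotropic voxel size in micrometres.
#' @param calibrated whether values are already Hounsfield units.
#' @return A [CTVolume-class] object.
#' @export
CTVolume <- function(voxels, voxelSizeUm = 35, calibrated = FALSE) {
  storage.mode(voxels) <- "double"
  new("CTVolume", voxels = voxels, voxelSizeUm = as.numeric(voxelSizeUm),
      calibrated = isTRUE(calibrated))
}

#' Construct a BinaryMask
#' @param mask logical 3D array in \code{[z, y, x]} layout.
#' @return A [BinaryMask-class] object.
#' @export
BinaryMask <- function(mask) {
  storage.mode(mask) <- "logical"
  new("BinaryMask", mask = mask)
}

#' Construct a CalibrationModel from phantom region means
#' @param waterGray mean grayscale of the water region (maps to 0 HU).
#' @param airGray mean grayscale of the air region (maps to -1000 HU).
#' @return A [CalibrationModel-class] object.
#' @export
CalibrationModel <- function(waterGray, airGray) {
  new("CalibrationModel", waterGray = as.numeric(waterGray),
      airGray = as.numeric(airGray))
}

#' Construct SegmentationParams
#'
#' Defaults follow the scanning mode: air threshold -580 HU for
#' euthanized scans, -383 HU for in vivo gated scans; border erosion
#' radius 10 px in both.
#'
#' @param mode \code{"euthanized"} or \code{"in_vivo"}.
#' @param airThresholdHU override the mode's default threshold.
#' @param erosionRadiusPx body-ROI border erosion radius in pixels.
#' @return A [SegmentationParams-class] object.
#' @export
SegmentationParams <- function(mode = c("euthanized", "in_vivo"),
                               airThresholdHU = NULL,
                               erosionRadiusPx = 10L) {
  mode <- match.arg(mode)
  if (is.null(airThresholdHU))
    airThresholdHU <- if (mode == "euthanized") -580 else -383
  new("SegmentationParams", airThresholdHU = as.numeric(airThresholdHU),
      erosionRadiusPx = as.integer(erosionRadiusPx), mode = mode)
}

#' Construct a BreathingTrace
#' @param timeS sample times in seconds.
#' @param displacement thorax-marker displacement (arbitrary units).
#' @return A [BreathingTrace-class] object.
#' @export
BreathingTrace <- function(timeS, displacement) {
  new("BreathingTrace", timeS = as.numeric(timeS),
      displacement = as.numeric(displacement))
}

#' @rdname CTVolume
#' @param object,x a package object.
#' @export
setGeneric("voxelData", function(object) standardGeneric("voxelData"))

#' @rdname CTVolume
#' @export
setMethod("voxelData", "CTVolume", function(object) object@voxels)

#' @rdname CTVolume
#' @export
setGeneric("voxelSizeUm", function(object) standardGeneric("voxelSizeUm"))

#' @rdname CTVolume
#' @export
setMethod("voxelSizeUm", "CTVolume", function(object) object@voxelSizeUm)

#' @rdname CTVolume
#' @export
setGeneric("isCalibrated", function(object) standardGeneric("isCalibrated"))

#' @rdname CTVolume
#' @export
setMethod("isCalibrated", "CTVolume", function(object) object@calibrated)

#' @rdname BinaryMask
#' @param object a BinaryMask.
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))

#' @rdname BinaryMask
#' @export
setMethod("maskArray", "BinaryMask", function(object) object@mask)

#' @rdname SegmentationResult-class
#' @param object a SegmentationResult.
#' @export
setGeneric("voxelCount", function(object) standardGeneric("voxelCount"))

#' @rdname SegmentationResult-class
#' @export
setMethod("voxelCount", "SegmentationResult", function(object) object@voxelCount)

#' @rdname SegmentationResult-class
#' @export
setGeneric("volumeMm3", function(object) standardGeneric("volumeMm3"))

#' @rdname SegmentationResult-class
#' @export
setMethod("volumeMm3", "SegmentationResult", function(object) object@volumeMm3)

#' @rdname SegmentationResult-class
#' @export
setGeneric("lungMask", function(object) standardGeneric("lungMask"))

#' @rdname SegmentationResult-class
#' @export
setMethod("lungMask", "SegmentationResult", function(object) object@lungMask)

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("CTVolume: %d x %d x %d voxels (z,y,x), %.4g um isotropic, %s\n",
              d[1], d[2], d[3], object@voxelSizeUm,
              if (object@calibrated) "calibrated (HU)" else "raw grayscale"))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("BinaryMask: %d x %d x %d, %d foreground voxels\n",
              d[1], d[2], d[3], sum(object@mask)))
})

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf("CalibrationModel: water %.4g -> 0 HU, air %.4g -> -1000 HU\n",
              object@waterGray, object@airGray))
})

setMethod("show", "SegmentationParams", function(object) {
  cat(sprintf(
    "SegmentationParams: mode %s, air threshold <= %.4g HU, erosion %d px\n",
    object@mode, object@airThresholdHU, object@erosionRadiusPx))
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf(
    "SegmentationResult: %d lung-air voxels = %.4g mm^3 (mode %s, threshold %.4g HU)\n",
    object@voxelCount, object@volumeMm3, object@params@mode,
    object@params@airThresholdHU))
})

setMethod("show", "PhaseBinning", function(object) {
  cat(sprintf("PhaseBinning: %d bins, occupancy [%s], %d outside cycles, %s\n",
              object@nBins, paste(object@occupancy, collapse = ", "),
              length(object@outsideIdx),
              if (object@valid) "valid" else "INVALID (<2 projections in a bin)"))
})

setMethod("show", "RespiratoryVolumes", function(object) {
  cat(sprintf("RespiratoryVolumes: EIV %.4g mm^3, EEV %.4g mm^3%s\n",
              object@eivMm3, object@eevMm3,
              if (object@consistent) "" else " [FLAG: EIV < EEV]"))
})

setMethod("show", "PVCurve", function(object) {
  cat(sprintf("PVCurve: %d points, %.4g-%.4g cmH2O\n",
              length(object@pressureCmH2O), min(object@pressureCmH2O),
              max(object@pressureCmH2O)))
})

setMethod("show", "RepeatabilityReport", function(object) {
  cat(sprintf(
    "RepeatabilityReport: sw %.6g, 95%% repeatability coefficient %.6g\n",
    object@sw, object@repeatabilityCoefficient))
  cat(sprintf("  mean-vs-SD Spearman r %.3f (p = %.3g), %d subjects / %d measurements\n",
              object@spearmanR, object@spearmanP, object@nSubjects,
              object@nMeasurements))
})

setMethod("show", "AgreementFit", function(object) {
  cat(sprintf("AgreementFit: y = %.4g + %.4g x, R^2 %.3f, slope p = %.3g\n",
              object@intercept, object@slope, object@rSquared, object@pValue))
})
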