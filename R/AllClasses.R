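#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib lungct, .registration = TRUE
NULL

#' CTVolume: a reconstructed tomogram volume
#'
#' A 3D voxel grid with isotropic voxel size.  Values are raw grayscale
#' indices straight from the reconstruction before calibration, and
#' Hounsfield units (HU) afterwards.  The array is stored with
#' \code{dim = c(nz, ny, nx)} and indexed \code{[z, y, x]}: \code{z} is
#' the slice (file) index, \code{y} the image row and \code{x} the image
#' column, all 1-based in R.
#'
#' @slot voxels 3D numeric array, \code{dim = c(nz, ny, nx)}.
#' @slot voxelSizeUm isotropic voxel edge length in micrometres
#'   (35 for the scanner protocol this package targets).
#' @slot calibrated logical; \code{TRUE} once values are in HU.
#' @export
setClass("CTVolume", representation(
  voxels = "array",
  voxelSizeUm = "numeric",
  calibrated = "logical"
))

setValidity("CTVolume", function(object) {
  d <- dim(object@voxels)
  if (length(d) != 3L || any(d < 1L))
    return("voxels must be a 3D array with all dimensions >= 1")
  if (length(object@voxelSizeUm) != 1L || !is.finite(object@voxelSizeUm) ||
      object@voxelSizeUm <= 0)
    return("voxelSizeUm must be a single positive number")
  if (length(object@calibrated) != 1L || is.na(object@calibrated))
    return("calibrated must be TRUE or FALSE")
  if (object@calibrated && any(!is.finite(object@voxels)))
    return("calibrated volumes must contain only finite HU values")
  TRUE
})

#' BinaryMask: a boolean voxel grid
#'
#' Logical 3D array aligned voxel-for-voxel with a [CTVolume], using the
#' same \code{[z, y, x]} layout.  Intermediate and final segmentation
#' products are all BinaryMask objects.
#'
#' @slot mask logical 3D array.
#' @export
setClass("BinaryMask", representation(mask = "array"))

setValidity("BinaryMask", function(object) {
  if (length(dim(object@mask)) != 3L || !is.logical(object@mask))
    return("mask must be a logical 3D array")
  if (anyNA(object@mask)) return("mask must not contain NA")
  TRUE
})

#' CalibrationModel: two-point grayscale-to-HU map
#'
#' Linear calibration anchored at the mean grayscale of a water region
#' (mapped to 0 HU) and an air region (mapped to -1000 HU), as measured
#' on a water/air phantom scan.
#'
#' @slot waterGray mean grayscale index of pure water.
#' @slot airGray mean grayscale index of pure air; must be below
#'   \code{waterGray}.
#' @export
setClass("CalibrationModel",
         representation(waterGray = "numeric", airGray = "numeric"))

setValidity("CalibrationModel", function(object) {
  if (length(object@waterGray) != 1L || length(object@airGray) != 1L ||
      !is.finite(object@waterGray) || !is.finite(object@airGray))
    return("waterGray and airGray must be single finite numbers")
  if (object@waterGray <= object@airGray)
    return("waterGray must exceed airGray (grayscale must increase with density)")
  TRUE
})

#' HUHistogram: full-stack histogram over [-1000, +1000] HU
#'
#' Counts of ROI voxels per 1-HU-wide bin.  Bins are half-open
#' \code{[h, h+1)} with the last bin \code{[999, 1000]} closed; voxels
#' outside the range are tallied in the underflow/overflow counters, so
#' counts + underflow + overflow always equals the ROI voxel count.
#'
#' @slot binEdges numeric vector of 2001 edges, -1000..1000.
#' @slot counts integer counts per bin (length 2000).
#' @slot underflow,overflow voxels below -1000 / above +1000 HU.
#' @slot roiVoxelCount total voxels tallied.
#' @export
setClass("HUHistogram", representation(
  binEdges = "numeric", counts = "numeric",
  underflow = "numeric", overflow = "numeric",
  roiVoxelCount = "numeric"
))

setValidity("HUHistogram", function(object) {
  if (length(object@binEdges) != length(object@counts) + 1L)
    return("binEdges must have one more element than counts")
  if (any(object@counts < 0) || object@underflow < 0 || object@overflow < 0)
    return("counts must be non-negative")
  tot <- sum(object@counts) + object@underflow + object@overflow
  if (tot != object@roiVoxelCount)
    return("counts + underflow + overflow must equal roiVoxelCount")
  TRUE
})

#' SegmentationParams: tuning of the aerated-lung segmentation
#'
#' @slot airThresholdHU HU at or below which a voxel counts as air:
#'   -580 for euthanized (ex vivo) scans, -383 for free-breathing
#'   (in vivo) scans where gated motion blur contaminates boundary
#'   voxels.
#' @slot erosionRadiusPx radius in pixels of the per-slice square
#'   erosion applied to the body ROI border (default 10).
#' @slot mode \code{"euthanized"} or \code{"in_vivo"}; the two modes
#'   differ only in the default threshold.
#' @export
setClass("SegmentationParams", representation(
  airThresholdHU = "numeric", erosionRadiusPx = "integer", mode = "character"
))

setValidity("SegmentationParams", function(object) {
  if (!object@mode %in% c("euthanized", "in_vivo"))
    return("mode must be 'euthanized' or 'in_vivo'")
  if (!is.finite(object@airThresholdHU) ||
      object@airThresholdHU <= -1000 || object@airThresholdHU >= 0)
    return("airThresholdHU must lie strictly between -1000 and 0")
  if (object@erosionRadiusPx < 0L)
    return("erosionRadiusPx must be >= 0")
  TRUE
})

#' SegmentationResult: output of the aerated-lung algorithm
#'
#' @slot lungMask final [BinaryMask] of aerated lung.
#' @slot bodyROI body region of interest (complement of external air).
#' @slot erodedROI body ROI after border erosion.
#' @slot voxelCount number of lung-air voxels.
#' @slot volumeMm3 \code{voxelCount * voxelSizeMm^3}.
#' @slot histogram full-stack [HUHistogram] of the body ROI.
#' @slot params the [SegmentationParams] used.
#' @export
setClass("SegmentationResult", representation(
  lungMask = "BinaryMask", bodyROI = "BinaryMask", erodedROI = "BinaryMask",
  voxelCount = "numeric", volumeMm3 = "numeric",
  histogram = "HUHistogram", params = "SegmentationParams"
))

setValidity("SegmentationResult", function(object) {
  if (object@voxelCount != sum(object@lungMask@mask))
    return("voxelCount must equal the number of TRUE voxels in lungMask")
  TRUE
})

#' BreathingTrace: thorax-marker displacement over time
#'
#' The 1-D pseudo-sinusoidal breathing signal extracted from the video
#' registration of thorax movement during acquisition.
#'
#' @slot timeS sample times in seconds, strictly increasing.
#' @slot displacement marker displacement, arbitrary units.
#' @export
setClass("BreathingTrace",
         representation(timeS = "numeric", displacement = "numeric"))

setValidity("BreathingTrace", function(object) {
  if (length(object@timeS) < 2L)
    return("a breathing trace needs at least 2 samples")
  if (length(object@timeS) != length(object@displacement))
    return("timeS and displacement must have equal length")
  if (any(diff(object@timeS) <= 0))
    return("timeS must be strictly increasing")
  TRUE
})

#' PhaseBinning: projections assigned to respiratory phase bins
#'
#' @slot nBins number of equal-length phase bins (default 4, bins 0..3).
#' @slot assignments integer bin per projection (0-based); NA for
#'   projections falling outside every detected cycle.
#' @slot occupancy projections per bin.
#' @slot outsideIdx indices (1-based) of projections outside all cycles.
#' @slot valid TRUE iff every bin holds at least 2 projections.
#' @export
setClass("PhaseBinning", representation(
  nBins = "integer", assignments = "integer", occupancy = "integer",
  outsideIdx = "integer", valid = "logical"
))

setValidity("PhaseBinning", function(object) {
  a <- object@assignments[!is.na(object@assignments)]
  if (length(a) && (min(a) < 0L || max(a) >= object@nBins))
    return("assignments must lie in [0, nBins)")
  if (sum(object@occupancy) != length(a))
    return("occupancy must sum to the number of assigned projections")
  TRUE
})

#' RespiratoryVolumes: per-bin aerated volumes with EIV/EEV
#'
#' End-inspiratory volume (EIV) is the aerated volume in bin 0 (earliest
#' inspiration); end-expiratory volume (EEV, the functional residual
#' volume FRV) is the bin 3 volume.  EEV is the preferred endpoint for
#' group comparisons because it measures air trapping and is insensitive
#' to anesthesia-induced gasping.
#'
#' @slot perBinVoxels,perBinMm3 aerated volume per bin.
#' @slot eivMm3,eevMm3 bin 0 and bin 3 volumes in mm^3.
#' @slot consistent FALSE when EIV < EEV, which flags a likely
#'   trough/peak sign-convention error in the gating.
#' @export
setClass("RespiratoryVolumes", representation(
  perBinVoxels = "numeric", perBinMm3 = "numeric",
  eivMm3 = "numeric", eevMm3 = "numeric", consistent = "logical"
))

#' PVCurve: post-sacrifice pressure-volume curve
#'
#' Aerated volume as a function of applied tracheal pressure, acquired
#' at decreasing pressures (30 down to 3 cmH2O) and stored sorted by
#' ascending pressure.
#'
#' @slot pressureCmH2O strictly increasing pressures.
#' @slot volume paired volumes (mm^3 or voxel counts).
#' @export
setClass("PVCurve",
         representation(pressureCmH2O = "numeric", volume = "numeric"))

setValidity("PVCurve", function(object) {
  if (length(object@pressureCmH2O) < 2L)
    return("a PV curve needs at least 2 points")
  if (length(object@pressureCmH2O) != length(object@volume))
    return("pressures and volumes must have equal length")
  if (any(diff(object@pressureCmH2O) <= 0))
    return("pressures must be strictly increasing with no duplicates")
  TRUE
})

#' RepeatabilityReport: Bland-Altman measurement-error summary
#'
#' @slot sw within-subject standard deviation (square root of the
#'   one-way ANOVA residual mean square, subject as factor).
#' @slot repeatabilityCoefficient \code{1.96 * sqrt(2) * sw}; 95\% of
#'   paired repeat measurements on one subject fall within this range.
#' @slot spearmanR,spearmanP Spearman correlation of per-subject mean
#'   vs SD (heteroscedasticity check).
#' @slot nSubjects,nMeasurements sizes after dropping unusable subjects.
#' @export
setClass("RepeatabilityReport", representation(
  sw = "numeric", repeatabilityCoefficient = "numeric",
  spearmanR = "numeric", spearmanP = "numeric",
  nSubjects = "integer", nMeasurements = "integer"
))

#' AgreementFit: linear-regression agreement with prediction bands
#'
#' @slot slope,intercept ordinary least squares coefficients.
#' @slot rSquared coefficient of determination.
#' @slot pValue two-sided p-value for the slope.
#' @slot predictionHalfWidth 95\% prediction-interval half-width at each
#'   observed x.
#' @slot fit the underlying \code{lm} fit.
#' @export
setClass("AgreementFit", representation(
  slope = "numeric", intercept = "numeric", rSquared = "numeric",
  pValue = "numeric", predictionHalfWidth = "numeric", fit = "ANY"
))
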