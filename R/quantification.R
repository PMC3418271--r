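## Post-sacrifice pressure-volume curves and their area under the curve.

#' Build a pressure-volume curve
#'
#' Accepts the acquisition order (decreasing pressures, 30 down to 3
#' cmH2O, applied via the tracheal cannula) and normalizes to ascending
#' pressure.  Arbitrary monotone pressure schedules are accepted.
#'
#' @param pressuresCmH2O applied airway pressures.
#' @param volumes paired aerated volumes (mm^3 or voxel counts).
#' @return A [PVCurve-class] sorted by ascending pressure.
#' @export
buildPVCurve <- function(pressuresCmH2O, volumes) {
  if (length(pressuresCmH2O) != length(volumes))
    stop("pressures and volumes must have equal length")
  if (length(pressuresCmH2O) < 2L)
    stop("a PV curve needs at least 2 points")
  if (anyDuplicated(pressuresCmH2O))
    stop("duplicate pressures in PV curve")
  ord <- order(pressuresCmH2O)
  new("PVCurve", pressureCmH2O = as.numeric(pressuresCmH2O[ord]),
      volume = as.numeric(volumes[ord]))
}

#' Area under a pressure-volume curve
#'
#' Trapezoidal area over the measured pressure range only; the curve is
#' not extrapolated below the lowest or above the highest pressure.
#'
#' @param curve a [PVCurve-class].
#' @return Area in volume-units times cmH2O.
#' @export
pvAUC <- function(curve) {
  stopifnot(is(curve, "PVCurve"))
  p <- curve@pressureCmH2O
  v <- curve@volume
  n <- length(p)
  sum(diff(p) * (v[-1] + v[-n]) / 2)
}

#' @describeIn buildPVCurve PV curve as a data.frame.
#' @param x a PVCurve.
#' @param row.names,optional,... ignored; for the generic.
#' @export
as.data.frame.PVCurve <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(pressureCmH2O = x@pressureCmH2O, volume = x@volume)
}
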