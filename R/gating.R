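## Retrospective respiratory gating: breathing-trace cycle detection,
## phase-bin assignment of projection timestamps, EIV/EEV bookkeeping.

dominantPeriod <- function(timeS, displacement) {
  # FFT peak of the detrended signal; assumes near-uniform sampling
  dt <- median(diff(timeS))
  x <- displacement - mean(displacement)
  n <- length(x)
  spec <- Mod(stats::fft(x))[2:floor(n / 2)]
  if (!length(spec) || all(spec == 0)) return(NA_real_)
  freq <- (seq_along(spec)) / (n * dt)
  1 / freq[which.max(spec)]
}

#' Detect respiratory cycles in a breathing trace
#'
#' The displacement signal is smoothed with a centered moving average
#' and cycle onsets are placed at its troughs (end-expiration, i.e. the
#' initiation of inspiration); each cycle spans trough to next trough.
#' Partial cycles before the first and after the last trough are
#' discarded because phase fraction is undefined there.
#'
#' @param trace a [BreathingTrace-class].
#' @param smoothingWindowS moving-average window in seconds; default
#'   \code{NULL} uses 25\% of the dominant (FFT-peak) period.
#' @param invert set TRUE when the marker signal has the opposite sign
#'   convention (peaks at end-expiration); the displacement is negated
#'   before trough detection.
#' @return data.frame with one row per cycle: \code{onsetTimeS},
#'   \code{durationS}.
#' @export
detectBreathCycles <- function(trace, smoothingWindowS = NULL,
                               invert = FALSE) {
  stopifnot(is(trace, "BreathingTrace"))
  y <- if (invert) -trace@displacement else trace@displacement
  t <- trace@timeS
  dt <- median(diff(t))
  period <- dominantPeriod(t, y)
  if (is.null(smoothingWindowS))
    smoothingWindowS <- if (is.finite(period)) 0.25 * period else 0
  k <- max(1L, round(smoothingWindowS / dt))
  if (k %% 2L == 0L) k <- k + 1L
  if (k > 1L) {
    sm <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
    # shrink the window at the ends instead of dropping samples
    half <- (k - 1L) %/% 2L
    n <- length(y)
    for (i in which(is.na(sm)))
      sm[i] <- mean(y[max(1L, i - half):min(n, i + half)])
  } else sm <- y
  n <- length(sm)
  isMin <- c(FALSE, sm[2:(n - 1)] < sm[1:(n - 2)] &
               sm[2:(n - 1)] <= sm[3:n], FALSE)
  troughs <- which(isMin)
  # enforce a refractory separation of half the dominant period,
  # keeping the deepest trough within each cluster
  if (length(troughs) > 1L && is.finite(period)) {
    minSep <- 0.5 * period
    keep <- troughs[1]
    for (i in troughs[-1]) {
      last <- keep[length(keep)]
      if (t[i] - t[last] >= minSep) keep <- c(keep, i)
      else if (sm[i] < sm[last]) keep[length(keep)] <- i
    }
    troughs <- keep
  }
  if (length(troughs) < 2L) stop("no respiratory cycles detected")
  onsets <- t[troughs]
  data.frame(onsetTimeS = onsets[-length(onsets)],
             durationS = diff(onsets))
}

#' Assign projection timestamps to respiratory phase bins
#'
#' A projection acquired at phase fraction \code{phi} within its cycle
#' (0 at the initiation of inspiration) lands in bin
#' \code{floor(nBins * phi)}: the cycle is divided into \code{nBins}
#' phases of identical length, bin 0 earliest-inspiration through bin
#' \code{nBins - 1} end-expiration.  Projections outside every detected
#' cycle are flagged in \code{outsideIdx}, not silently dropped.  The
#' binning is \code{valid} only when every bin holds at least 2
#' projections.
#'
#' @param cycles data.frame from [detectBreathCycles()].
#' @param projectionTimesS acquisition timestamps in seconds.
#' @param nBins number of phase bins (default 4).
#' @return A [PhaseBinning-class].
#' @export
assignPhaseBins <- function(cycles, projectionTimesS, nBins = 4L) {
  if (!nrow(cycles)) stop("no respiratory cycles supplied")
  nBins <- as.integer(nBins)
  stopifnot(nBins >= 1L)
  ends <- cycles$onsetTimeS + cycles$durationS
  assignments <- rep(NA_integer_, length(projectionTimesS))
  for (i in seq_along(projectionTimesS)) {
    tp <- projectionTimesS[i]
    j <- which(cycles$onsetTimeS <= tp & tp < ends)
    if (length(j)) {
      j <- j[1]
      phi <- (tp - cycles$onsetTimeS[j]) / cycles$durationS[j]
      assignments[i] <- min(as.integer(floor(nBins * phi)), nBins - 1L)
    }
  }
  occupancy <- tabulate(assignments + 1L, nbins = nBins)
  valid <- all(occupancy >= 2L)
  if (!valid) {
    thin <- which(occupancy < 2L) - 1L
    warning("bin(s) ", paste(thin, collapse = ", "),
            " have fewer than 2 projections")
  }
  new("PhaseBinning", nBins = nBins, assignments = assignments,
      occupancy = as.integer(occupancy),
      outsideIdx = which(is.na(assignments)), valid = valid)
}

#' Per-bin aerated volumes with EIV/EEV
#'
#' Takes the per-bin segmentation results in bin order (bin 0 first)
#' and reports end-inspiratory volume (bin 0) and end-expiratory volume
#' (last bin).  A consistency flag is lowered when EIV < EEV, which
#' suggests an inverted gating sign convention.
#'
#' @param perBinResults list of [SegmentationResult-class], one per bin
#'   in bin order.
#' @param nBins expected number of bins (default 4).
#' @return A [RespiratoryVolumes-class].
#' @export
respiratoryVolumes <- function(perBinResults, nBins = 4L) {
  if (length(perBinResults) != nBins)
    stop(sprintf("expected %d per-bin results, got %d", nBins,
                 length(perBinResults)))
  stopifnot(all(vapply(perBinResults, is, logical(1), "SegmentationResult")))
  vox <- vapply(perBinResults, voxelCount, numeric(1))
  mm3 <- vapply(perBinResults, volumeMm3, numeric(1))
  eiv <- mm3[1]
  eev <- mm3[nBins]
  consistent <- eiv >= eev
  if (!consistent)
    warning("EIV < EEV: check the gating sign convention")
  new("RespiratoryVolumes", perBinVoxels = vox, perBinMm3 = mm3,
      eivMm3 = eiv, eevMm3 = eev, consistent = consistent)
}
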