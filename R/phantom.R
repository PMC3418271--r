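## Seeded synthetic data: water/air calibration phantom, 4-phase digital
## mouse thorax with fibrosis/emphysema transforms and exact ground
## truth, and pseudo-sinusoidal breathing traces.  Ground truth is
## defined on the noiseless geometry; recovery tolerances absorb noise.

#' Water/air calibration phantom
#'
#' Concentric cylinders along z emulating an air-filled tube inside a
#' water-filled tube: grayscale \code{airGray} inside the inner
#' cylinder, \code{waterGray} in the annulus, air again outside.
#' Region masks mark pure-air and pure-water voxels (a safety margin
#' inside each region), from which calibration anchors are measured.
#'
#' @param dims volume dimensions \code{c(nz, ny, nx)}.
#' @param waterGray,airGray true grayscale levels (defaults 81.32 / 0,
#'   the scanner's stored indices for water and air).
#' @param noiseSdGray Gaussian grayscale noise SD.
#' @param airRadiusFrac,waterRadiusFrac cylinder radii as fractions of
#'   the smaller in-plane dimension.
#' @param seed RNG seed for the noise.
#' @return list: \code{volume} (raw [CTVolume-class]), \code{waterMask},
#'   \code{airMask} ([BinaryMask-class]).
#' @export
makeCalibrationPhantom <- function(dims = c(40L, 64L, 64L),
                                   waterGray = 81.32, airGray = 0,
                                   noiseSdGray = 0,
                                   airRadiusFrac = 0.12,
                                   waterRadiusFrac = 0.40,
                                   seed = 1L) {
  if (airRadiusFrac >= waterRadiusFrac)
    stop("air region must be smaller than the water region")
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  r2 <- outer((seq_len(ny) - cy)^2, (seq_len(nx) - cx)^2, "+")
  rr <- sqrt(r2) / min(ny, nx)
  slice <- matrix(airGray, ny, nx)
  slice[rr <= waterRadiusFrac] <- waterGray
  slice[rr <= airRadiusFrac] <- airGray
  vox <- aperm(array(slice, dim = c(ny, nx, nz)), c(3, 1, 2))
  set.seed(seed)
  if (noiseSdGray > 0)
    vox <- vox + array(stats::rnorm(length(vox), 0, noiseSdGray), dim(vox))
  margin <- 0.8  # stay clear of region boundaries
  airSlice <- rr <= airRadiusFrac * margin
  waterSlice <- rr > airRadiusFrac / margin & rr <= waterRadiusFrac * margin
  list(volume = CTVolume(vox, calibrated = FALSE),
       waterMask = BinaryMask(aperm(array(waterSlice, c(ny, nx, nz)), c(3, 1, 2))),
       airMask = BinaryMask(aperm(array(airSlice, c(ny, nx, nz)), c(3, 1, 2))))
}

ellipsoidMask <- function(dims, center, semi) {
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  dz <- (seq_len(nz) - center[1]) / semi[1]
  dy <- (seq_len(ny) - center[2]) / semi[2]
  dx <- (seq_len(nx) - center[3]) / semi[3]
  q <- outer(outer(dz^2, dy^2, "+"), dx^2, "+")
  q <= 1
}

#' Digital mouse-thorax phantom with ground truth
#'
#' Builds one calibrated volume per respiratory phase: a soft-tissue
#' body (elliptical cylinder) surrounded by external air and resting
#' over a bed slab, containing two air-filled lung ellipsoids joined by
#' a central bronchial bridge.  Lungs deflate from phase 0 (EIV,
#' largest) to phase 3 (EEV); fibrosis replaces a fraction of the
#' lung-air voxels with patchy tissue-density consolidations, and
#' emphysema scales the lung-air compartment volume.  Optional
#' sub-threshold "speckle" pockets (-600 HU) outside the lung exercise
#' the largest-component sweep.  Ground truth (per-phase aerated-lung
#' masks and volumes) is recorded on the noiseless geometry before
#' Gaussian HU noise is added.
#'
#' @param dims volume dimensions \code{c(nz, ny, nx)} (default 200^3).
#' @param voxelSizeUm isotropic voxel size (default 35).
#' @param noiseSdHu Gaussian HU noise SD (default 20).
#' @param fibrosisFraction fraction of lung-air voxels consolidated
#'   (0..1).
#' @param emphysemaFactor multiplicative increase of lung-air volume
#'   (>= 1).
#' @param addSpeckles add sub-threshold air pockets outside the lung.
#' @param lungAirHU,tissueHU,bedHU,speckleHU,externalAirHU HU levels.
#' @param phases which phases to generate (subset of 0:3; default all).
#' @param inflationFraction EIV/EEV volume ratio minus 1 (default
#'   0.45: phase-0 lung air is 45\% larger than phase 3).
#' @param seed RNG seed; noise, fibrosis patches and speckles use
#'   deterministic sub-streams so matched seeds share geometry and
#'   noise across severity settings.
#' @return list: \code{volumes} (named list of calibrated
#'   [CTVolume-class], one per phase), \code{groundTruth} with
#'   \code{lungAirMasks}, \code{volVoxels}, \code{volMm3},
#'   \code{bodyMask}, \code{speckleMask}.
#' @export
makeThoraxPhantom <- function(dims = c(200L, 200L, 200L),
                              voxelSizeUm = 35,
                              noiseSdHu = 20,
                              fibrosisFraction = 0,
                              emphysemaFactor = 1,
                              addSpeckles = FALSE,
                              lungAirHU = -1000, tissueHU = 40,
                              bedHU = 100, speckleHU = -600,
                              externalAirHU = -1000,
                              phases = 0:3,
                              inflationFraction = 0.45,
                              seed = 1L) {
  stopifnot(fibrosisFraction >= 0, fibrosisFraction <= 1,
            emphysemaFactor >= 1, all(phases %in% 0:3))
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  bodySemi <- c(Inf, 0.38 * ny, 0.44 * nx)  # cylinder along z
  bodyCenter <- c(0, 0.50 * ny, 0.50 * nx)
  dy <- (seq_len(ny) - bodyCenter[2]) / bodySemi[2]
  dx <- (seq_len(nx) - bodyCenter[3]) / bodySemi[3]
  bodySlice <- outer(dy^2, dx^2, "+") <= 1
  body <- aperm(array(bodySlice, c(ny, nx, nz)), c(3, 1, 2))

  bed <- array(FALSE, dims)
  bedY <- seq(round(0.90 * ny), round(0.94 * ny))
  bedX <- seq(round(0.15 * nx), round(0.85 * nx))
  bed[, bedY, bedX] <- TRUE
  bed <- bed & !body

  lungCenters <- list(c(0.50 * nz, 0.48 * ny, 0.38 * nx),
                      c(0.50 * nz, 0.48 * ny, 0.62 * nx))
  eevSemi <- c(0.30 * nz, 0.17 * ny, 0.105 * nx)
  phaseScale <- (1 + inflationFraction * (3 - 0:3) / 3)^(1 / 3) *
    emphysemaFactor^(1 / 3)

  # fibrosis patch stream in lung-relative coordinates: identical for a
  # given seed, consumed as a prefix, so severity is monotone by
  # construction on matched seeds
  set.seed(seed + 1L)
  nPatch <- 20000L
  patchLung <- sample(1:2, nPatch, replace = TRUE)
  u <- matrix(stats::rnorm(3 * nPatch), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * stats::runif(nPatch)^(1 / 3)  # unit ball
  patchRFrac <- stats::runif(nPatch, 0.10, 0.22)

  # speckle positions drawn regardless of addSpeckles so the RNG
  # streams match between paired phantoms
  set.seed(seed + 2L)
  nSpeck <- 8L
  # placed in the tissue band above the lungs: inside the body, clear of
  # the lung compartment at every phase and emphysema setting
  speckPos <- cbind(z = stats::runif(nSpeck, 0.2 * nz, 0.8 * nz),
                    y = stats::runif(nSpeck, 0.20 * ny, 0.25 * ny),
                    x = stats::runif(nSpeck, 0.30 * nx, 0.70 * nx))
  speckR <- stats::runif(nSpeck, 2, 3.5)

  speckleMask <- array(FALSE, dims)
  if (addSpeckles) {
    for (s in seq_len(nSpeck))
      speckleMask <- speckleMask |
        ellipsoidMask(dims, speckPos[s, ], rep(speckR[s], 3))
    speckleMask <- speckleMask & body
  }

  volumes <- list()
  gtMasks <- list()
  gtVox <- numeric(0)
  for (p in phases) {
    semi <- eevSemi * phaseScale[p + 1]
    lung <- ellipsoidMask(dims, lungCenters[[1]], semi) |
      ellipsoidMask(dims, lungCenters[[2]], semi)
    # bronchial bridge joining the two lungs into one 3D component
    zc <- round(lungCenters[[1]][1]); yc <- round(lungCenters[[1]][2])
    xr <- seq(round(lungCenters[[1]][3]), round(lungCenters[[2]][3]))
    lung[(zc - 3):(zc + 3), (yc - 3):(yc + 3), xr] <- TRUE
    if (any(lung & !body)) stop("lung compartment exceeds the body")

    fibrosis <- array(FALSE, dims)
    if (fibrosisFraction > 0) {
      target <- round(fibrosisFraction * sum(lung))
      removed <- 0L
      for (i in seq_len(nPatch)) {
        if (removed >= target) break
        ctr <- lungCenters[[patchLung[i]]] + u[i, ] * semi
        pr <- patchRFrac[i] * min(semi)
        # carve the spherical patch inside its bounding box only
        zr <- max(1L, floor(ctr[1] - pr)):min(nz, ceiling(ctr[1] + pr))
        yr <- max(1L, floor(ctr[2] - pr)):min(ny, ceiling(ctr[2] + pr))
        xr <- max(1L, floor(ctr[3] - pr)):min(nx, ceiling(ctr[3] + pr))
        q <- outer(outer(((zr - ctr[1]) / pr)^2, ((yr - ctr[2]) / pr)^2,
                         "+"), ((xr - ctr[3]) / pr)^2, "+")
        patch <- (q <= 1) & lung[zr, yr, xr] & !fibrosis[zr, yr, xr]
        nNew <- sum(patch)
        if (nNew == 0L) next
        if (removed + nNew > target) {
          # trim the last patch voxel-wise to hit the target exactly
          idx <- which(patch)
          patch[idx[(target - removed + 1L):nNew]] <- FALSE
          nNew <- target - removed
        }
        fibrosis[zr, yr, xr] <- fibrosis[zr, yr, xr] | patch
        removed <- removed + nNew
      }
    }
    lungAir <- lung & !fibrosis

    hu <- array(externalAirHU, dims)
    hu[body] <- tissueHU
    hu[bed] <- bedHU
    if (addSpeckles) hu[speckleMask & !lung] <- speckleHU
    hu[lungAir] <- lungAirHU
    # fibrotic consolidations stay at tissue density

    set.seed(seed + 10L + p)
    if (noiseSdHu > 0)
      hu <- hu + array(stats::rnorm(length(hu), 0, noiseSdHu), dims)

    key <- paste0("bin", p)
    volumes[[key]] <- CTVolume(hu, voxelSizeUm = voxelSizeUm,
                               calibrated = TRUE)
    gtMasks[[key]] <- BinaryMask(lungAir)
    gtVox[key] <- sum(lungAir)
  }
  list(volumes = volumes,
       groundTruth = list(
         lungAirMasks = gtMasks,
         volVoxels = gtVox,
         volMm3 = gtVox * (voxelSizeUm / 1000)^3,
         bodyMask = BinaryMask(body),
         speckleMask = BinaryMask(speckleMask)))
}

#' Pseudo-sinusoidal breathing trace
#'
#' Sinusoidal thorax-marker displacement at the given respiratory rate,
#' sampled at \code{samplingHz}, with optional Gaussian noise.
#'
#' @param rateHz respiratory rate in Hz (> 0).
#' @param durationS trace duration in seconds (> 2 / rateHz).
#' @param noiseSd Gaussian noise SD in amplitude units (signal
#'   amplitude is 1).
#' @param seed RNG seed.
#' @param samplingHz sampling rate (default 100).
#' @return A [BreathingTrace-class].
#' @export
makeBreathingTrace <- function(rateHz, durationS, noiseSd = 0, seed = 1L,
                               samplingHz = 100) {
  if (rateHz <= 0) stop("respiratory rate must be positive")
  if (durationS <= 2 / rateHz)
    stop("duration must exceed two respiratory periods (2 / rateHz)")
  t <- seq(0, durationS, by = 1 / samplingHz)
  set.seed(seed)
  y <- sin(2 * pi * rateHz * t)
  if (noiseSd > 0) y <- y + stats::rnorm(length(t), 0, noiseSd)
  BreathingTrace(t, y)
}

#' Convert a calibrated volume back to stored grayscale
#'
#' Inverse of [calibrateToHU()] under the given anchors, rounded to
#' integer grayscale indices and clamped at zero, as a scanner would
#' store them.  Used to produce raw slice stacks from simulated
#' phantoms.
#'
#' @param volume a calibrated [CTVolume-class].
#' @param model a [CalibrationModel-class].
#' @return A raw (uncalibrated) [CTVolume-class] of integer grayscale.
#' @export
huToGrayscale <- function(volume, model) {
  stopifnot(is(volume, "CTVolume"), is(model, "CalibrationModel"))
  if (!volume@calibrated) stop("volume is not calibrated")
  g <- model@waterGray +
    volume@voxels * (model@waterGray - model@airGray) / 1000
  CTVolume(pmax(round(g), 0), voxelSizeUm = volume@voxelSizeUm,
           calibrated = FALSE)
}
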