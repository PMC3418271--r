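test_that("calibration phantom anchors its own grayscale regions", {
  ph <- makeCalibrationPhantom(dims = c(10L, 48L, 48L), noiseSdGray = 0)
  water <- mean(voxelData(ph$volume)[maskArray(ph$waterMask)])
  air <- mean(voxelData(ph$volume)[maskArray(ph$airMask)])
  model <- CalibrationModel(water, air)
  hu <- calibrateToHU(ph$volume, model)
  expect_equal(mean(voxelData(hu)[maskArray(ph$waterMask)]), 0)
  expect_equal(mean(voxelData(hu)[maskArray(ph$airMask)]), -1000)

  # same seed twice -> bit-identical
  a <- makeCalibrationPhantom(noiseSdGray = 5, seed = 3)
  b <- makeCalibrationPhantom(noiseSdGray = 5, seed = 3)
  expect_identical(voxelData(a$volume), voxelData(b$volume))

  # noisy region means land within 3 sigma / sqrt(N) of the anchors
  nz <- makeCalibrationPhantom(dims = c(20L, 64L, 64L), noiseSdGray = 10,
                               seed = 8)
  nW <- sum(maskArray(nz$waterMask)); nA <- sum(maskArray(nz$airMask))
  expect_lt(abs(mean(voxelData(nz$volume)[maskArray(nz$waterMask)]) - 81.32),
            3 * 10 / sqrt(nW))
  expect_lt(abs(mean(voxelData(nz$volume)[maskArray(nz$airMask)]) - 0),
            3 * 10 / sqrt(nA))

  expect_error(makeCalibrationPhantom(airRadiusFrac = 0.45,
                                      waterRadiusFrac = 0.40),
               "smaller than the water region")
})

test_that("thorax phantom ground truth tracks severity by construction", {
  dims <- c(70L, 70L, 70L)
  norm <- makeThoraxPhantom(dims = dims, seed = 5, phases = 3,
                            noiseSdHu = 0)
  fib <- makeThoraxPhantom(dims = dims, seed = 5, phases = 3,
                           noiseSdHu = 0, fibrosisFraction = 0.3)
  # 30% consolidation removes exactly that fraction (one-voxel quantum)
  expect_lte(abs(fib$groundTruth$volVoxels - 0.7 * norm$groundTruth$volVoxels),
             1)
  # fibrotic ground truth is a subset of the normal lung air
  expect_false(any(maskArray(fib$groundTruth$lungAirMasks$bin3) &
                     !maskArray(norm$groundTruth$lungAirMasks$bin3)))

  # emphysema dose response is strictly ordered
  e0 <- makeThoraxPhantom(dims = dims, seed = 5, phases = 3, noiseSdHu = 0)
  e1 <- makeThoraxPhantom(dims = dims, seed = 5, phases = 3, noiseSdHu = 0,
                          emphysemaFactor = 1.2)
  e2 <- makeThoraxPhantom(dims = dims, seed = 5, phases = 3, noiseSdHu = 0,
                          emphysemaFactor = 1.4)
  expect_lt(e0$groundTruth$volVoxels, e1$groundTruth$volVoxels)
  expect_lt(e1$groundTruth$volVoxels, e2$groundTruth$volVoxels)

  # determinism
  again <- makeThoraxPhantom(dims = dims, seed = 5, phases = 3)
  first <- makeThoraxPhantom(dims = dims, seed = 5, phases = 3)
  expect_identical(voxelData(first$volumes$bin3),
                   voxelData(again$volumes$bin3))

  # phases deflate monotonically: EIV (bin 0) largest, EEV (bin 3) smallest
  all4 <- makeThoraxPhantom(dims = dims, seed = 6, noiseSdHu = 0)
  vols <- all4$groundTruth$volVoxels
  expect_true(all(diff(vols) < 0))
  expect_gte(vols["bin0"], vols["bin3"])

  # ground-truth lung air never overlaps the speckle mask
  sp <- makeThoraxPhantom(dims = dims, seed = 7, phases = 3,
                          addSpeckles = TRUE)
  expect_false(any(maskArray(sp$groundTruth$speckleMask) &
                     maskArray(sp$groundTruth$lungAirMasks$bin3)))

  # an oversized lung compartment is rejected
  expect_error(makeThoraxPhantom(dims = c(40L, 40L, 40L),
                                 emphysemaFactor = 8),
               "exceeds the body")
})

test_that("breathing trace generator matches its closed form", {
  tr <- makeBreathingTrace(2, 10)
  expect_equal(tr@displacement, sin(2 * pi * 2 * tr@timeS))
  expect_equal(nrow(detectBreathCycles(tr)), 19)

  a <- makeBreathingTrace(2, 10, noiseSd = 0.1, seed = 4)
  b <- makeBreathingTrace(2, 10, noiseSd = 0.1, seed = 4)
  expect_identical(a@displacement, b@displacement)

  expect_error(makeBreathingTrace(0, 10), "must be positive")
  expect_error(makeBreathingTrace(2, 0.5), "duration")
})

test_that("grayscale round trip preserves HU within quantization", {
  ph <- makeThoraxPhantom(dims = c(40L, 40L, 40L), seed = 9, phases = 3,
                          noiseSdHu = 0)
  model <- CalibrationModel(81.32, 0)
  raw <- huToGrayscale(ph$volumes$bin3, model)
  expect_false(isCalibrated(raw))
  expect_true(all(voxelData(raw) == round(voxelData(raw))))
  back <- calibrateToHU(raw, model)
  # one grayscale step is 1000 / 81.32 HU; rounding stays within half
  quantum <- 1000 / 81.32
  expect_lt(max(abs(voxelData(back) - voxelData(ph$volumes$bin3))),
            quantum / 2 + 1e-9)
})
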