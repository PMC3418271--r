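test_that("air thresholding includes the boundary and matches a scan", {
  expect_true(all(maskArray(
    thresholdAir(huVolume(array(-1000, c(2, 3, 3))), -580))))
  expect_false(any(maskArray(
    thresholdAir(huVolume(array(0, c(2, 3, 3))), -580))))
  # boundary inclusion: HU == threshold is air
  expect_true(all(maskArray(
    thresholdAir(huVolume(array(-580, c(1, 2, 2))), -580))))

  set.seed(5)
  vox <- array(runif(6 * 7 * 8, -1000, 0), c(6, 7, 8))
  m <- maskArray(thresholdAir(huVolume(vox), -580))
  # independent voxel-by-voxel scan
  n <- 0L
  for (i in seq_along(vox)) if (vox[i] <= -580) n <- n + 1L
  expect_equal(sum(m), n)

  # monotone in the threshold: lowering it never adds voxels
  m2 <- maskArray(thresholdAir(huVolume(vox), -700))
  expect_false(any(m2 & !m))

  expect_error(thresholdAir(CTVolume(array(0, c(1, 1, 1))), -580),
               "calibrated")
})

test_that("despeckle keeps border-connected air and removes pores", {
  # one slice: air frame at the border, solid ring of tissue, enclosed
  # air disk in the middle
  sl <- matrix(TRUE, 20, 20)
  sl[5:16, 5:16] <- FALSE        # tissue block
  sl[9:12, 9:12] <- TRUE         # enclosed pore
  air <- BinaryMask(array(sl, c(1, 20, 20)))
  ext <- maskArray(externalAirMask(air))[1, , ]
  expect_true(all(ext[1, ]))                 # frame kept
  expect_false(any(ext[9:12, 9:12]))         # pore removed
  expect_equal(sum(ext), sum(sl) - 16)

  # an all-air slice touches the border and is fully kept
  allAir <- BinaryMask(array(TRUE, c(1, 8, 8)))
  expect_true(all(maskArray(externalAirMask(allAir))))

  # seeded random slices agree with an iterative flood-fill oracle
  set.seed(9)
  for (rep in 1:5) {
    sl <- matrix(runif(30 * 30) < 0.45, 30, 30)
    got <- maskArray(externalAirMask(BinaryMask(array(sl, c(1, 30, 30)))))[1, , ]
    expect_identical(got, floodBorderAirOracle2D(sl))
  }
})

test_that("body ROI is the complement of external air", {
  sl <- matrix(TRUE, 20, 20)
  sl[5:16, 5:16] <- FALSE
  sl[9:12, 9:12] <- TRUE
  ext <- externalAirMask(BinaryMask(array(sl, c(1, 20, 20))))
  roi <- maskArray(bodyROI(ext))
  expect_identical(roi, !maskArray(ext))
  expect_true(all(roi[1, 9:12, 9:12]))   # enclosed pore inside the ROI

  # no external air -> ROI is the full field of view
  roi2 <- bodyROI(BinaryMask(array(FALSE, c(2, 5, 5))))
  expect_true(all(maskArray(roi2)))

  # the whole FOV external air -> no subject
  expect_error(bodyROI(BinaryMask(array(TRUE, c(2, 5, 5)))),
               "no subject in field of view")
})

test_that("ROI erosion is a per-slice square erosion of the given radius", {
  sq <- array(FALSE, c(1, 50, 50))
  sq[1, 11:40, 11:40] <- TRUE        # solid 30x30 square
  er <- maskArray(erodeROI(BinaryMask(sq), 10L))
  expect_equal(sum(er), 100)         # 10x10 survives
  expect_true(all(er[1, 21:30, 21:30]))

  sm <- array(FALSE, c(1, 30, 30))
  sm[1, 8:22, 8:22] <- TRUE          # 15x15 vanishes under r = 10
  expect_error(erodeROI(BinaryMask(sm), 10L), "vanished under erosion")

  # radius 0 is the identity
  expect_identical(maskArray(erodeROI(BinaryMask(sq), 0L)), sq)

  # irregular slices (solid block with punched holes): erosion equals
  # thresholding the Chebyshev distance transform at > r
  set.seed(21)
  for (r in c(1L, 3L)) {
    sl <- matrix(FALSE, 40, 40)
    sl[4:37, 4:37] <- TRUE
    holes <- cbind(sample(4:37, 10), sample(4:37, 10))
    sl[holes] <- FALSE
    got <- maskArray(erodeROI(BinaryMask(array(sl, c(1, 40, 40))), r))[1, , ]
    expect_identical(got, chebyshevDistOracle2D(sl) > r)
  }
})

test_that("the sweep keeps exactly the largest 26-connected component", {
  m <- array(FALSE, c(10, 10, 10))
  m[2:5, 2:6, 2:6] <- TRUE           # 100 voxels
  m[8, 8:9, 8] <- TRUE               # 2 voxels (diagonal gap from first)
  kept <- maskArray(largestComponent3D(BinaryMask(m)))
  expect_equal(sum(kept), 100)
  expect_false(any(kept[8, , ]))

  # idempotent on a single component
  expect_identical(maskArray(largestComponent3D(BinaryMask(kept))), kept)

  # equal sizes: the component with the lexicographically smallest
  # (z, y, x) voxel wins
  tie <- array(FALSE, c(4, 6, 6))
  tie[2, 2, 2] <- TRUE               # seed (2,2,2)
  tie[2, 5, 5] <- TRUE               # seed (2,5,5) - loses
  keptTie <- maskArray(largestComponent3D(BinaryMask(tie)))
  expect_true(keptTie[2, 2, 2])
  expect_false(keptTie[2, 5, 5])

  expect_error(largestComponent3D(BinaryMask(array(FALSE, c(2, 2, 2)))),
               "empty segmentation")
})

test_that("3D labeling agrees with an exhaustive graph-components oracle", {
  skip_if_not_installed("igraph")
  set.seed(13)
  m <- array(runif(12^3) < 0.25, c(12, 12, 12))
  m[1, 1, 1] <- TRUE
  got <- maskArray(largestComponent3D(BinaryMask(m)))
  orc <- componentsOracle3D(m)
  sizes <- table(orc$membership)
  biggest <- as.integer(names(sizes)[which.max(sizes)])
  inBig <- orc$coords[orc$membership == biggest, , drop = FALSE]
  expect_equal(sum(got), max(sizes))
  expect_true(all(got[inBig]))
})

test_that("the full algorithm recovers phantom lungs and ignores speckle", {
  ph <- makeThoraxPhantom(dims = c(80L, 80L, 80L), seed = 2, phases = 3)
  res <- segmentAeratedLung(ph$volumes$bin3)
  gt <- ph$groundTruth
  expect_lt(abs(voxelCount(res) - gt$volVoxels) / gt$volVoxels, 0.05)

  # nesting: lung mask within eroded ROI within body ROI
  lung <- maskArray(lungMask(res))
  expect_true(all(maskArray(res@erodedROI)[lung]))
  expect_true(all(maskArray(res@bodyROI)[maskArray(res@erodedROI)]))

  # exactly one 26-connected component
  expect_identical(maskArray(largestComponent3D(lungMask(res))), lung)

  # units conserved between voxels and mm^3
  expect_equal(volumeMm3(res), voxelCount(res) * (35 / 1000)^3)

  # sub-threshold speckle pockets outside the lung change nothing
  phS <- makeThoraxPhantom(dims = c(80L, 80L, 80L), seed = 2, phases = 3,
                           addSpeckles = TRUE)
  expect_gt(sum(maskArray(phS$groundTruth$speckleMask)), 0)
  resS <- segmentAeratedLung(phS$volumes$bin3)
  expect_identical(maskArray(lungMask(resS)), lung)

  # a solid-tissue subject with no lung yields an empty segmentation
  solid <- array(-1000, c(20, 30, 30))
  solid[, 8:22, 8:22] <- 40
  expect_error(
    segmentAeratedLung(huVolume(solid),
                       SegmentationParams(erosionRadiusPx = 2L)),
    "empty segmentation")
})

test_that("in vivo mode only raises the air threshold", {
  pIn <- SegmentationParams("in_vivo")
  pEx <- SegmentationParams("euthanized")
  expect_equal(pIn@airThresholdHU, -383)
  expect_equal(pEx@airThresholdHU, -580)
  expect_equal(pIn@erosionRadiusPx, pEx@erosionRadiusPx)

  # parenchyma-level lung air (-650) is captured ex vivo and in vivo
  ph <- makeThoraxPhantom(dims = c(80L, 80L, 80L), seed = 4, phases = 3,
                          lungAirHU = -650, noiseSdHu = 10)
  gt <- ph$groundTruth$volVoxels
  rIn <- segmentAeratedLung(ph$volumes$bin3, SegmentationParams("in_vivo"))
  expect_lt(abs(voxelCount(rIn) - gt) / gt, 0.05)
})
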