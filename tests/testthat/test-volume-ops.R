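test_that("VOI extraction preserves geometry bookkeeping", {
  v <- VascVolume(array(seq_len(6 * 7 * 8), c(6, 7, 8)),
                  spacing = c(0.5, 0.5, 0.5), origin = c(1, 2, 3))
  full <- extractVOI(v, c(physExtent(v)[1, ], physExtent(v)[2, ]))
  expect_identical(voxelData(full), voxelData(v))
  expect_identical(voxelOrigin(full), voxelOrigin(v))
  # single-voxel region at the correct physical origin
  one <- extractVOI(v, c(2.1, 3.1, 4.1, 2.4, 3.4, 4.4))
  expect_equal(dim(voxelData(one)), c(2L, 2L, 2L))
  expect_equal(voxelOrigin(one), c(2.0, 3.0, 4.0))
  expect_error(extractVOI(v, c(50, 50, 50, 60, 60, 60)), "intersect")
})

test_that("tricubic resampling reproduces constants and linear ramps", {
  v <- VascVolume(array(150, c(12, 12, 12)), spacing = c(1, 1, 1))
  r <- resampleTricubic(v, 0.4)
  expect_equal(range(voxelData(r)), c(150, 150), tolerance = 1e-12)
  # axis-aligned linear ramp reproduced away from borders
  ramp <- VascVolume(array(rep(0:11, 144), c(12, 12, 12)), spacing = c(1, 1, 1))
  rr <- resampleTricubic(ramp, 0.3)
  d <- dim(voxelData(rr))
  interior <- voxelData(rr)[8:(d[1] - 8), 8:(d[2] - 8), 8:(d[3] - 8)]
  truth <- (seq_len(d[1]) - 1) * 0.3
  expect_lt(max(abs(sweep(interior, 1L, truth[8:(d[1] - 8)], "-"))), 1e-6)
  expect_message(resampleTricubic(v, 2), "coarser")
})

test_that("resampled phantom keeps the analytic axis value", {
  ph <- torusFixture()
  p <- ph$truth@centerline(11)
  voi <- extractVOI(ph$volume, c(p - 4, p + 4))
  aux <- resampleTricubic(voi, 0.2)
  expect_lt(abs(sampleGrid(aux, p) - 225), 2)
})

test_that("tricubic resampling commutes with axis permutation", {
  set.seed(8)
  v <- VascVolume(array(rnorm(9 * 9 * 9), c(9, 9, 9)), spacing = c(1, 1, 1))
  r1 <- voxelData(resampleTricubic(v, 0.5))
  vp <- VascVolume(aperm(voxelData(v), c(2, 3, 1)), spacing = c(1, 1, 1))
  r2 <- voxelData(resampleTricubic(vp, 0.5))
  expect_equal(aperm(r1, c(2, 3, 1)), r2, tolerance = 1e-12)
})

test_that("threshold segmentation is monotone and excludes background", {
  ph <- torusFixture()
  m100 <- segmentThreshold(ph$volume, 100)
  m150 <- segmentThreshold(ph$volume, 150)
  expect_true(all(voxelData(m100)[voxelData(m150)]))   # 150-mask subset of 100-mask
  # phantom background (75 HU) excluded for any valid threshold
  bg <- voxelData(ph$volume) <= 75
  expect_false(any(voxelData(m100) & bg))
  expect_warning(segmentThreshold(ph$volume, 80), "outside")
  # mask-derived radius ~ true R at the boundary threshold
  dm <- distanceMap(m150)
  expect_lt(abs(max(voxelData(dm)) - 2), 0.6)
})

test_that("distance map equals the brute-force EDT and honors anisotropy", {
  set.seed(1)
  d <- c(7, 6, 5)
  sp <- c(0.5, 0.7, 1.1)
  m <- array(runif(prod(d)) < 0.4, d)
  m[1, 1, 1] <- FALSE                     # keep at least one background voxel
  dm <- distanceMap(new("SegmentationMask", data = m, spacing = sp,
                        origin = c(0, 0, 0), thresholdLow = 1))
  bg <- which(!m, arr.ind = TRUE)
  bf <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) if (m[i, j, k])
    bf[i, j, k] <- sqrt(min(((bg[, 1] - i) * sp[1])^2 +
                            ((bg[, 2] - j) * sp[2])^2 +
                            ((bg[, 3] - k) * sp[3])^2))
  expect_equal(voxelData(dm), bf, tolerance = 1e-12)
})

test_that("distance map agrees with the independent EBImage transform", {
  # EBImage::distmap works frame-wise in 2-D; on a z-invariant mask the 3-D
  # transform provably equals the per-slice 2-D one, giving a dual route
  set.seed(2)
  m2 <- matrix(runif(16 * 14) < 0.55, 16, 14)
  m2[1, ] <- FALSE
  m3 <- array(rep(m2, 9), c(16, 14, 9))
  dm <- distanceMap(new("SegmentationMask", data = m3, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0), thresholdLow = 1))
  oracle <- EBImage::distmap(m2 + 0)
  expect_equal(voxelData(dm)[, , 5], matrix(as.numeric(oracle), 16, 14),
               tolerance = 1e-6)
})

test_that("distance map closed forms: ball center, single voxel, Lipschitz", {
  d <- c(21, 21, 21)
  m <- array(FALSE, d)
  for (i in 1:21) for (j in 1:21) for (k in 1:21)
    if ((i - 11)^2 + (j - 11)^2 + (k - 11)^2 <= 64) m[i, j, k] <- TRUE
  dm <- distanceMap(new("SegmentationMask", data = m, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0), thresholdLow = 1))
  expect_lt(abs(voxelData(dm)[11, 11, 11] - 8), 0.5)
  # single-voxel mask: ~ half the smallest voxel extent... distance to the
  # nearest background voxel center = the smallest spacing
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  dm1 <- distanceMap(new("SegmentationMask", data = one,
                         spacing = c(0.4, 0.6, 0.9), origin = c(0, 0, 0),
                         thresholdLow = 1))
  expect_equal(voxelData(dm1)[3, 3, 3], 0.4)
  # 1-Lipschitz w.r.t. physical distance (sampled voxel pairs)
  set.seed(3)
  v <- voxelData(dm)
  idx <- cbind(sample(21, 200, TRUE), sample(21, 200, TRUE), sample(21, 200, TRUE))
  jdx <- cbind(sample(21, 200, TRUE), sample(21, 200, TRUE), sample(21, 200, TRUE))
  dd <- sqrt(rowSums((idx - jdx)^2))
  expect_true(all(abs(v[idx] - v[jdx]) <= dd + 1e-9))
  expect_error(distanceMap(new("SegmentationMask",
      data = array(FALSE, c(3, 3, 3)), spacing = c(1, 1, 1),
      origin = c(0, 0, 0), thresholdLow = 1)), "empty")
})

test_that("NIfTI write/read round-trips data and geometry", {
  set.seed(4)
  v <- VascVolume(array(rnorm(4 * 5 * 6), c(4, 5, 6)),
                  spacing = c(0.5, 0.6, 0.7), origin = c(1, 2, 3))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolume(v, path)
  v2 <- readVolume(path)
  expect_equal(voxelData(v2), voxelData(v))
  # header stores geometry as float32: exact to single precision
  expect_equal(voxelSpacing(v2), voxelSpacing(v), tolerance = 1e-6)
  expect_equal(voxelOrigin(v2), voxelOrigin(v), tolerance = 1e-6)
})

test_that("VOI locality: measurements match between full volume and VOI", {
  ph <- torusFixture()
  s <- 13
  p <- ph$truth@centerline(s)
  n <- ph$truth@geometry$tangent(s)
  voi <- extractVOI(ph$volume, c(p - 6, p + 6))
  csFull <- measureVessel(ph$volume, p, n)
  csVoi <- measureVessel(voi, p, n)
  expect_equal(csVoi@dAvg, csFull@dAvg, tolerance = 1e-6)
  expect_equal(csVoi@area, csFull@area, tolerance = 1e-6)
})
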