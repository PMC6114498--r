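test_that("sigmoid HU profile has the exact boundary, axis and far-field values", {
  expect_equal(huProfile(5, C = 150, R = 5, a = 10), 150)
  expect_equal(huProfile(3, C = 120, R = 3, a = 2), 120)
  expect_equal(huProfile(0, C = 150, R = 5, a = 10), 225, tolerance = 1e-15)
  expect_equal(huProfile(1e6, C = 150, R = 5, a = 10), 75)
  # bounded in (C/2, 1.5C) and non-increasing
  r <- seq(0, 20, by = 0.01)
  v <- huProfile(r, C = 150, R = 5, a = 10)
  expect_true(all(v > 75 - 1e-12 & v < 225 + 1e-12))
  expect_true(all(diff(v) <= 1e-12))
  expect_error(huProfile(1, C = 150, R = -1, a = 10), "positive")
  expect_error(huProfile(1, C = 150, R = 5, a = 0), "positive")
})

test_that("spatial brush is idempotent and commutes over strokes", {
  v0 <- VascVolume(array(75, c(24, 24, 24)), spacing = c(0.5, 0.5, 0.5))
  p1 <- c(5, 6, 6); p2 <- c(6.5, 6, 6)
  v1 <- paintBrush(v0, p1, radius = 1.5)
  expect_equal(voxelData(paintBrush(v1, p1, radius = 1.5)), voxelData(v1))
  a <- paintBrush(paintBrush(v0, p1, 1.5), p2, 1.5)
  b <- paintBrush(paintBrush(v0, p2, 1.5), p1, 1.5)
  expect_equal(voxelData(a), voxelData(b))
  # per-voxel max of the individual strokes
  s1 <- voxelData(paintBrush(v0, p1, 1.5))
  s2 <- voxelData(paintBrush(v0, p2, 1.5))
  expect_equal(voxelData(a), pmax(s1, s2))
  # voxel at distance R from the stroke center carries ~C
  g <- expand.grid(i = 1:24, j = 1:24, k = 1:24)
  d <- sqrt((0.5 * (g$i - 1) - p1[1])^2 + (0.5 * (g$j - 1) - p1[2])^2 +
            (0.5 * (g$k - 1) - p1[3])^2)
  at <- which(abs(d - 1.5) < 1e-9)
  expect_true(length(at) > 0)
  expect_equal(unname(s1[cbind(g$i[at], g$j[at], g$k[at])]),
               rep(150, length(at)), tolerance = 1e-12)
  expect_warning(paintBrush(v0, c(100, 0, 0), 1), "outside")
})

test_that("torus phantom carries the analytic profile and ground truth", {
  ph <- torusFixture()
  gt <- ph$truth
  expect_equal(gt@arcRange[2], 2 * pi * 20)
  # on-axis HU ~ 1.5C, far field C/2
  expect_equal(sampleGrid(ph$volume, gt@centerline(7)), 225, tolerance = 0.01)
  expect_equal(sampleGrid(ph$volume, voxelOrigin(ph$volume) + 2), 75)
  # maximal inscribed radius ~ D/2 (threshold at the painted boundary)
  dm <- distanceMap(segmentThreshold(ph$volume, 150))
  expect_lt(abs(max(voxelData(dm)) - 2), 0.6)
  # ground-truth radius and curvature
  expect_equal(gt@radius(3), 2)
  expect_equal(gt@curvature, 1 / 20)
  expect_equal(gt@torsion, 0)
  expect_error(makeTorus(D = 4, R1 = 50, extent = 100), "fit")
})

test_that("helix ground truth matches the closed-form Frenet quantities", {
  ph <- makeHelix(D = 1.5, R1 = 12, R2 = 9, extent = 40)
  b <- 9 / (2 * pi)
  expect_equal(ph$truth@curvature, 12 / (12^2 + b^2))
  expect_equal(ph$truth@torsion, b / (12^2 + b^2))
  # one full turn: arc length 2*pi*sqrt(R1^2 + b^2)
  expect_equal(ph$truth@arcRange[2], 2 * pi * sqrt(12^2 + b^2))
  # degenerate rise: planar circle limit
  ph0 <- makeHelix(D = 1.5, R1 = 12, R2 = 1e-9, extent = 40)
  expect_equal(ph0$truth@curvature, 1 / 12, tolerance = 1e-12)
  expect_equal(ph0$truth@torsion, 0, tolerance = 1e-9)
  # chordal arc length of dense samples agrees with the closed form
  s <- seq(0, ph$truth@arcRange[2], by = 0.05)
  pts <- t(vapply(s, ph$truth@centerline, numeric(3)))
  expect_rel(max(arcLength(pts)), ph$truth@arcRange[2], 1e-3)
})

test_that("model grid enumeration applies the self-overlap rejection rule", {
  full <- enumerateModelGrid("torus", seq(1, 5, 0.25), seq(5, 30, 1))
  expect_equal(attr(full, "rawCount"), 442)
  expect_length(full, 412)
  expect_true(all(vapply(full, function(s) s@R1 >= 2 * s@D, logical(1))))
  d5 <- enumerateModelGrid("torus", 5, seq(5, 30, 1))
  expect_length(d5, 21)
  d1 <- enumerateModelGrid("torus", 1, seq(5, 30, 1))
  expect_length(d1, 26)
  hx <- diameterValidationGrid("helix")
  expect_length(hx, 1086)
  expect_true(all(vapply(hx, function(s) s@R2 >= 2 * s@D, logical(1))))
  # deterministic lexicographic ordering
  dd <- vapply(full, function(s) s@D, numeric(1))
  expect_true(all(diff(dd) >= 0))
  expect_length(enumerateModelGrid("torus", numeric(0), 5), 0)
})

test_that("ABZ sampling is uniform within ranges and reproducible", {
  s1 <- sampleABZ(70, seed = 99)
  s2 <- sampleABZ(70, seed = 99)
  expect_length(s1, 70)
  expect_identical(vapply(s1, function(p) p@A1, numeric(1)),
                   vapply(s2, function(p) p@A1, numeric(1)))
  rg <- abzRanges()
  for (p in s1) {
    expect_true(p@A1 >= rg$A1[1] && p@A1 <= rg$A1[2])
    expect_true(p@D1 >= rg$D1[1] && p@D1 <= rg$D1[2])
    expect_true(p@Dan >= rg$Dan[1] && p@Dan <= rg$Dan[2])
  }
  # degenerate ranges give the single deterministic set
  rg0 <- lapply(rg, function(r) c(mean(r), mean(r)))
  p0 <- sampleABZ(1, ranges = rg0, seed = 1)[[1]]
  expect_equal(p0@A1, mean(rg$A1))
  expect_warning(ABZParams(A1 = 100, A2 = 45), "outside anatomical range")
})

test_that("bifurcation phantom ground truth matches its construction", {
  p <- ABZParams(A1 = 45, A2 = 45, A1pl = 0, A2pl = 0)
  ph <- makeBifurcation(p, includeAneurysm = FALSE, extent = 60)
  g <- ph$truth@geometry
  expect_equal(g$trueBA, 90, tolerance = 1e-9)
  expect_equal(g$trueVA, c(45, 45), tolerance = 1e-9)
  # in-plane construction: branch directions perpendicular to the normal
  expect_equal(angleBetween(g$branchDirs[[1]], g$trueDPN), 90, tolerance = 1e-9)
  expect_equal(unname(g$trueCoI[c("b1", "b2")]), c(0, 0), tolerance = 1e-12)
  # stored direction vectors reproduce the stored angles
  expect_lt(abs(angleBetween(g$branchDirs[[1]], g$branchDirs[[2]]) - g$trueBA),
            1e-9)
  expect_lt(abs(angleBetween(g$trunkDir, g$branchDirs[[1]]) - g$trueVA[1]),
            1e-9)
  # tilted construction: VA = acos(cos A cos Apl)
  p2 <- ABZParams(A1 = 30, A2 = 60, A1pl = 10, A2pl = -5)
  g2 <- makeBifurcation(p2, includeAneurysm = FALSE, extent = 60)$truth@geometry
  expect_equal(g2$trueVA[1], acos(cos(30 * pi / 180) * cos(10 * pi / 180)) * 180 / pi,
               tolerance = 1e-9)
  # aneurysm painting raises HU at the sac center
  ph3 <- makeBifurcation(p, includeAneurysm = TRUE, extent = 60)
  sac <- g$apex + c(0, 0, p@Dan / 2)
  expect_gt(sampleGrid(ph3$volume, sac), 220)
})

test_that("ground truth serializes as a JSON sidecar", {
  ph <- makeHelix(D = 1.5, R1 = 12, R2 = 9, extent = 40)
  path <- withr::local_tempfile(fileext = ".json")
  writeGroundTruth(ph$truth, path, arcStep = 1)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(js$kind, "helix")
  expect_equal(nrow(js$samples), length(seq(0, ph$truth@arcRange[2], by = 1)))
  expect_equal(unname(unlist(js$samples[1, c("x", "y", "z")])),
               unname(ph$truth@centerline(0)), tolerance = 1e-12)
})
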