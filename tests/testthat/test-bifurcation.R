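# Exact constructed polylines: a straight stem along +z splitting into two
# straight branches, with per-point radii. No voxel pipeline involved.
makeY <- function(a1 = 45, a2 = 45, tilt1 = 0, tilt2 = 0, step = 0.25,
                  stem = 14, branch = 18, r = 1.5) {
  deg <- pi / 180
  u <- function(a, tl, s) c(s * sin(a * deg) * cos(tl * deg), sin(tl * deg),
                            cos(a * deg) * cos(tl * deg))
  u1 <- u(a1, tilt1, +1); u2 <- u(a2, tilt2, -1)
  sS <- seq(0, stem, by = step)
  sB <- seq(step, branch, by = step)
  apex <- c(0, 0, stem)
  A <- rbind(cbind(0, 0, sS), t(apex + outer(u1, sB)))
  B <- rbind(cbind(0, 0, sS), t(apex + outer(u2, sB)))
  list(curveA = Centerline(A, radius = rep(r, nrow(A))),
       curveB = Centerline(B, radius = rep(r, nrow(B))),
       apex = apex, u1 = u1, u2 = u2)
}

test_that("split point localizes the apex of a V division", {
  y <- makeY()
  sp <- findSplitPoint(y$curveA, y$curveB, zoneConfig())
  expect_lt(sqrt(sum((sp$T0 - y$apex)^2)), 0.3)
  # curves that never approach: no division
  far <- Centerline(cbind(10, 10, seq(0, 12, 0.25)))
  expect_error(findSplitPoint(y$curveA, far, zoneConfig()), "no division")
  expect_error(findSplitPoint(y$curveA, y$curveA, zoneConfig()), "degenerate")
  # enlarging d moves the split distally (monotone in d)
  z1 <- findSplitPoint(y$curveA, y$curveB, zoneConfig(d = 0.2))
  z2 <- findSplitPoint(y$curveA, y$curveB, zoneConfig(d = 0.6))
  expect_gte(z2$arcA, z1$arcA)
})

test_that("symmetric Y zones have equidistant branch 0-points", {
  y <- makeY(40, 40)
  parts <- splitDivision(y$curveA, y$curveB, zoneConfig())
  z <- buildZone(parts$trunk, parts$branch1, parts$branch2, parts$T0,
                 zoneConfig())
  d1 <- sqrt(sum((z@Br1[1, ] - z@T0)^2))
  d2 <- sqrt(sum((z@Br2[1, ] - z@T0)^2))
  expect_lt(abs(d1 - d2), 0.3)
  # measured angles match the construction
  expect_equal(z@BA, 80, tolerance = 1)
  expect_equal(z@VA1, 40, tolerance = 1)
  expect_equal(z@VA2, 40, tolerance = 1)
  # nPoints = 2 yields exactly the points the VDVs need
  z2 <- buildZone(parts$trunk, parts$branch1, parts$branch2, parts$T0,
                  zoneConfig(nPoints = 2L))
  expect_equal(nrow(z2@Br1), 2L)
  expect_equal(nrow(z2@Tr), 2L)
})

test_that("division plane passes through the 0-points with a signed normal", {
  dp <- divisionPlane(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                      flowDirection = c(0, 0, 1))
  expect_equal(dp$normal, c(0, 0, 1))
  expect_error(divisionPlane(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               "degenerate plane")
  # in-plane construction: DPN close to the construction plane normal
  y <- makeY(50, 35)
  parts <- splitDivision(y$curveA, y$curveB, zoneConfig())
  z <- buildZone(parts$trunk, parts$branch1, parts$branch2, parts$T0,
                 zoneConfig())
  expect_lt(min(angleBetween(z@DPN, c(0, 1, 0)),
                180 - angleBetween(z@DPN, c(0, 1, 0))), 3)
})

test_that("angles follow the directional-vector arithmetic", {
  y <- makeY(45, 45)
  parts <- splitDivision(y$curveA, y$curveB, zoneConfig())
  z <- buildZone(parts$trunk, parts$branch1, parts$branch2, parts$T0,
                 zoneConfig())
  ang <- zoneAngles(z)
  expect_equal(unname(ang["BA"]), 90, tolerance = 1)
  expect_equal(unname(ang["VA1"]), 45, tolerance = 1)
  # pure vector checks
  expect_equal(angleBetween(c(1, 1, 0), c(1, -1, 0)), 90)
  expect_equal(angleBetween(c(1, 0, 0), c(1, 1, 0)), 45)
  expect_error(angleBetween(c(0, 0, 0), c(1, 0, 0)), "zero")
})

test_that("angles are invariant under rigid motions of the zone curves", {
  y <- makeY(55, 30, tilt1 = 8, tilt2 = -4)
  parts <- splitDivision(y$curveA, y$curveB, zoneConfig())
  z0 <- buildZone(parts$trunk, parts$branch1, parts$branch2, parts$T0,
                  zoneConfig())
  th <- 0.7; ax <- vasctree:::unitv(c(1, 2, 3))
  rot <- function(p) vasctree:::rotateAbout(p, ax, th) + c(5, -3, 2)
  rotCl <- function(cl) Centerline(t(apply(clPoints(cl), 1, rot)),
                                   radius = clRadius(cl))
  zr <- buildZone(rotCl(parts$trunk), rotCl(parts$branch1),
                  rotCl(parts$branch2), rot(parts$T0), zoneConfig())
  expect_equal(zr@BA, z0@BA, tolerance = 1e-6)
  expect_equal(zr@VA1, z0@VA1, tolerance = 1e-6)
  expect_equal(zr@VA2, z0@VA2, tolerance = 1e-6)
  expect_equal(zr@CoIT, z0@CoIT, tolerance = 1e-6)
})

test_that("coplanarity index folds to the acute angle and spans [0, 1]", {
  expect_equal(coplanarityIndex(c(0, 0, 1), c(0, 0, 1)), 1)
  expect_equal(coplanarityIndex(c(0, 0, 1), c(0, 0, -2)), 1)  # acute fold
  expect_equal(coplanarityIndex(c(1, 0, 0), c(0, 0, 1)), 0)
  expect_equal(coplanarityIndex(vasctree:::unitv(c(1, 0, 1)), c(0, 0, 1)), 0.5)
  expect_error(coplanarityIndex(c(0, 0, 0), c(0, 0, 1)), "zero")
  # monotone decreasing in the acute angle
  ang <- seq(0, pi / 2, length.out = 20)
  coi <- vapply(ang, function(t)
      coplanarityIndex(c(sin(t), 0, cos(t)), c(0, 0, 1)), numeric(1))
  expect_true(all(diff(coi) < 0))
  # exposed in-plane convention is the complement
  expect_equal(coplanarityIndex(c(1, 0, 0), c(0, 0, 1), "in-plane"), 1)
})

test_that("dominance goes to the branch with the larger mean radius", {
  y <- makeY(45, 45)
  b1 <- y$curveA; b2 <- y$curveB
  fat <- Centerline(clPoints(b1), radius = rep(2, nrow(clPoints(b1))))
  thin <- Centerline(clPoints(b2), radius = rep(1.2, nrow(clPoints(b2))))
  parts <- splitDivision(fat, thin, zoneConfig())
  z <- suppressWarnings(      # fat branch is short for 4 points at 3 radii
    buildZone(parts$trunk, parts$branch1, parts$branch2, parts$T0,
              zoneConfig()))
  expect_equal(z@dominant, 1L)
  rep1 <- zoneReport(z)
  expect_equal(rep1$dominant, 1)
  expect_equal(rep1$VA_dom, z@VA1)
  expect_equal(rep1$CoI_ndom, z@CoI2)
})

test_that("the true division is selected against aneurysm-departure zones", {
  y <- makeY()
  parts <- splitDivision(y$curveA, y$curveB, zoneConfig())
  z <- buildZone(parts$trunk, parts$branch1, parts$branch2, parts$T0,
                 zoneConfig())
  zFar <- z; zFar@T0 <- z@T0 + c(0, 0, 8)
  # single zone without aneurysm curves: returned unchanged
  sel <- selectTrueDivision(list(z), c(0, 0, 0), list(c(2L, 3L)))
  expect_identical(sel$division, z)
  expect_null(sel$aneurysmStem)
  # the furthest zone carries the type-1 curve: flagged as aneurysm stem
  sel2 <- selectTrueDivision(list(z, zFar), c(0, 0, 0),
                             list(c(2L, 3L), c(2L, 1L)))
  expect_identical(sel2$aneurysmStem, zFar)
  expect_identical(sel2$division, z)
  expect_error(selectTrueDivision(list(z), c(0, 0, 0), list(c(1L, 1L))),
               "no non-aneurysm")
  expect_error(selectTrueDivision(list(), c(0, 0, 0), list()), "no zones")
})

test_that("curve types annotate centerlines", {
  cl <- Centerline(rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_true(is.na(curveType(cl)))
  curveType(cl) <- 1L
  expect_equal(curveType(cl), 1L)
})
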