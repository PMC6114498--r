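# analytic helix sample shared by several blocks
helixPts <- function(a = 20, b = 3, turns = 1.5, n = 300) {
  t <- seq(0, turns * 2 * pi, length.out = n)
  cbind(a * cos(t), a * sin(t), b * t)
}

test_that("straight points reproduce a line with zero curvature", {
  s <- seq(0, 30, by = 0.5)
  pts <- cbind(s, 0.5 * s, -0.25 * s)
  sp <- fitSpline(Centerline(pts, radius = rep(1.5, length(s))))
  expect_lt(sp@residualRMS, 1e-8)
  ct <- curvatureTorsion(sp, seq(1, sp@totalLength - 1, by = 1))
  expect_lt(max(ct$kappa), 1e-8)
  expect_equal(max(abs(ct$tau)), 0)       # kappa floor zeroes the torsion
})

test_that("circle and helix fits recover the closed-form Frenet quantities", {
  # circle of radius 20
  t <- seq(0, 1.6 * pi, length.out = 260)
  circ <- cbind(20 * cos(t), 20 * sin(t), 0)
  spc <- fitSpline(Centerline(circ, radius = rep(2, nrow(circ))))
  ctc <- curvatureTorsion(spc, seq(2, spc@totalLength - 2, by = 0.5))
  expect_lt(max(abs(ctc$kappa - 1 / 20)) / (1 / 20), 0.02)
  expect_lt(max(abs(ctc$tau)), 1e-6)      # planar curve: zero torsion
  # circular helix a = 20, b = 3
  sph <- fitSpline(Centerline(helixPts(), radius = rep(2, 300)))
  cth <- curvatureTorsion(sph, seq(5, sph@totalLength - 5, by = 0.5))
  k0 <- 20 / 409; t0 <- 3 / 409
  expect_lt(max(abs(cth$kappa - k0)) / k0, 0.02)
  expect_lt(max(abs(cth$tau - t0)) / t0, 0.02)
})

test_that("joints are C3 within tolerance", {
  sp <- fitSpline(Centerline(helixPts(), radius = rep(2, 300)))
  expect_gt(length(sp@segments), 2L)      # several joints exist
  jArc <- approx(sp@arcTable[, 1], sp@arcTable[, 2],
                 xout = sp@breaks[2:(length(sp@breaks) - 1)])$y
  eps <- 1e-6
  for (s in jArc) {
    for (ord in 0:3) {
      lo <- evaluateSpline(sp, s - eps, ord)
      hi <- evaluateSpline(sp, s + eps, ord)
      ref <- sqrt(sum(lo^2))
      expect_lt(sqrt(sum((hi - lo)^2)) / max(ref, 1e-9), 1e-4)
    }
    d3 <- vasctree:::splineDerivsU(sp, c(s - eps, s + eps))$r3
    expect_lt(sqrt(sum((d3[2, ] - d3[1, ])^2)) /
              max(sqrt(sum(d3[1, ]^2)), 1e-9), 1e-6)
  }
})

test_that("C2-only joints leak torsion jumps that C3 removes", {
  cl <- Centerline(helixPts(), radius = rep(2, 300))
  jumpAt <- function(sp) {
    jArc <- approx(sp@arcTable[, 1], sp@arcTable[, 2],
                   xout = sp@breaks[2:(length(sp@breaks) - 1)])$y
    max(vapply(jArc, function(s)
      abs(curvatureTorsion(sp, s + 1e-4)$tau -
          curvatureTorsion(sp, s - 1e-4)$tau), numeric(1)))
  }
  j2 <- jumpAt(fitSpline(cl, continuity = 2L))
  j3 <- jumpAt(fitSpline(cl, continuity = 3L))
  expect_gt(j2, 1e-6)
  expect_lt(j3, 1e-7)        # solver round-off only
  expect_gt(j2 / j3, 100)    # C3 removes the jump, not merely shrinks it
})

test_that("evaluation interpolates endpoints and yields unit tangents", {
  pts <- helixPts()
  sp <- fitSpline(Centerline(pts, radius = rep(2, 300)))
  expect_equal(c(evaluateSpline(sp, 0, 0)), unname(pts[1, ]), tolerance = 1e-9)
  expect_equal(c(evaluateSpline(sp, sp@totalLength, 0)),
               unname(pts[nrow(pts), ]), tolerance = 1e-9)
  tg <- evaluateSpline(sp, c(10, 40, 80), 1)
  expect_equal(sqrt(rowSums(tg^2)), rep(1, 3), tolerance = 1e-9)
  # derivatives consistent with central differences
  h <- 1e-3
  for (s in c(15, 55)) {
    fd1 <- (evaluateSpline(sp, s + h, 0) - evaluateSpline(sp, s - h, 0)) / (2 * h)
    expect_equal(c(fd1), c(evaluateSpline(sp, s, 1)), tolerance = 1e-4)
    fd2 <- (evaluateSpline(sp, s + h, 1) - evaluateSpline(sp, s - h, 1)) / (2 * h)
    expect_equal(c(fd2), c(evaluateSpline(sp, s, 2)), tolerance = 1e-3)
  }
  expect_error(evaluateSpline(sp, sp@totalLength + 1, 0), "outside")
  expect_error(evaluateSpline(sp, -1, 0), "outside")
})

test_that("least-squares fitting smooths noisy input", {
  set.seed(6)
  t <- seq(0, 1.5 * pi, length.out = 200)
  clean <- cbind(20 * cos(t), 20 * sin(t), 0)
  noise <- 0.05
  noisy <- clean + cbind(rnorm(200, 0, noise) * cos(t),
                         rnorm(200, 0, noise) * sin(t), 0)
  sp <- fitSpline(Centerline(noisy, radius = rep(2, 200)))
  s <- seq(1, sp@totalLength - 1, by = 0.5)
  fitted <- evaluateSpline(sp, s, 0)
  resid <- sqrt((sqrt(fitted[, 1]^2 + fitted[, 2]^2) - 20)^2 + fitted[, 3]^2)
  expect_lt(sqrt(mean(resid^2)) / noise, 1)   # smoother than the input noise
})

test_that("curvature and torsion are rigid-motion invariant", {
  pts <- helixPts(a = 12, b = 2, n = 200)
  cl <- Centerline(pts, radius = rep(1.5, 200))
  sp0 <- fitSpline(cl)
  ax <- vasctree:::unitv(c(2, -1, 1))
  moved <- t(apply(pts, 1, function(p)
      vasctree:::rotateAbout(p, ax, 1.1) + c(4, 5, -6)))
  sp1 <- fitSpline(Centerline(moved, radius = rep(1.5, 200)))
  s <- seq(5, min(sp0@totalLength, sp1@totalLength) - 5, by = 2)
  c0 <- curvatureTorsion(sp0, s)
  c1 <- curvatureTorsion(sp1, s)
  expect_equal(c1$kappa, c0$kappa, tolerance = 1e-9)
  expect_equal(c1$tau, c0$tau, tolerance = 1e-9)
})

test_that("arc statistics summarize constant-curvature curves exactly", {
  sp <- fitSpline(Centerline(helixPts(), radius = rep(2, 300)))
  st <- arcStats(sp, c(10, sp@totalLength - 10))
  k0 <- 20 / 409; t0 <- 3 / 409
  expect_rel(st@Kmax, k0, 0.02)
  expect_rel(st@Kav, k0, 0.02)
  expect_rel(st@Tav, t0, 0.02)
  expect_gte(st@Kmax, st@Kav)
  # straight tube: all three ~ 0
  line <- cbind(seq(0, 30, 0.5), 0, 0)
  stl <- arcStats(fitSpline(Centerline(line, radius = rep(1.5, nrow(line)))))
  expect_lt(stl@Kmax, 1e-8)
  expect_equal(stl@Tav, 0)
  # circle arc: Kav = 1/R, Tav ~ 0
  t <- seq(0, pi, length.out = 150)
  circ <- cbind(15 * cos(t), 15 * sin(t), 0)
  stc <- arcStats(fitSpline(Centerline(circ, radius = rep(1.5, 150))))
  expect_rel(stc@Kav, 1 / 15, 0.02)
  expect_lt(stc@Tav, 1e-6)
  expect_error(arcStats(sp, c(5, 5)), "empty")
})

test_that("control-point count adapts to the local radius", {
  pts <- helixPts()
  nseg <- function(r) length(fitSpline(Centerline(pts, radius = rep(r, 300)))@segments)
  expect_gte(nseg(1), nseg(2))
  expect_gte(nseg(2), nseg(4))
  expect_gt(nseg(1), nseg(4))
})

test_that("splines serialize as JSON with control points and joints", {
  sp <- fitSpline(Centerline(helixPts(n = 120), radius = rep(2, 120)))
  path <- withr::local_tempfile(fileext = ".json")
  writeSpline(sp, path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(js$degree, 6L)
  expect_equal(length(js$segments), length(sp@segments))
  expect_equal(js$totalLength, sp@totalLength)
})
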