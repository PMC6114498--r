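# Perpendicular cross-section analysis: plane orientation, geometric center,
# ray-cast border tracing with neighbor-vessel handling, border smoothing and
# diameter/area measurement.

#' Cross-section measurement configuration
#'
#' HU thresholds follow the vessel-core / region-growing scheme: the core of
#' the vessel is the in-plane connected region with values in
#' [\code{Cmin}, \code{Cmax}]; rays march outward until the profile ends
#' (drops below \code{Odv}) or, with neighbor detection on, until the valley
#' before an adjacent vessel (a local minimum followed by a rise above
#' \code{Mmin}).
#'
#' @param Cmin,Cmax HU range of the vessel core.
#' @param Mmin HU lower threshold of the border area of adjacent vessels.
#' @param Odv HU lower threshold ending the outward march.
#' @param nRays number of border directions (step 2 pi / nRays).
#' @param neighborDetection stop at the inter-vessel valley?
#' @param smoothingWindow odd window for circular border smoothing.
#' @param marchStep ray sampling step, mm.
#' @param maxMarch maximal ray length, mm.
#' @param gridStep,gridHalfWidth in-plane sampling grid for the core search,
#'   mm.
#' @param lookAhead distance after a drop searched for a neighbor rise, mm.
#' @param riseTol minimal HU rise above a valley that flags a neighbor.
#' @return Named list of validated settings.
#' @export
crossSectionConfig <- function(Cmin = 170, Cmax = 1500, Mmin = 150,
                               Odv = 160, nRays = 36L,
                               neighborDetection = TRUE,
                               smoothingWindow = 5L, marchStep = 0.1,
                               maxMarch = 10, gridStep = 0.1,
                               gridHalfWidth = 5, lookAhead = 2,
                               riseTol = 15) {
    if (Cmin >= Cmax) stop("Cmin must be < Cmax")
    if (nRays < 8L) stop("nRays must be >= 8")
    if (smoothingWindow %% 2L != 1L) stop("smoothingWindow must be odd")
    list(Cmin = Cmin, Cmax = Cmax, Mmin = Mmin, Odv = Odv,
         nRays = as.integer(nRays), neighborDetection = neighborDetection,
         smoothingWindow = as.integer(smoothingWindow),
         marchStep = marchStep, maxMarch = maxMarch, gridStep = gridStep,
         gridHalfWidth = gridHalfWidth, lookAhead = lookAhead,
         riseTol = riseTol)
}

#' Geometric center of the vessel in a measuring plane
#'
#' Samples the plane through \code{click} with normal \code{normal} on a
#' regular in-plane grid, keeps values in the core range
#' [\code{Cmin}, \code{Cmax}], labels connected components, and returns the
#' intensity-weighted center of gravity of the component containing the
#' click, in global coordinates.
#'
#' @param volume a \linkS4class{VascVolume}.
#' @param normal unit plane normal.
#' @param click 3-D point in the plane, inside the vessel core.
#' @param cfg a [crossSectionConfig()].
#' @return Numeric(3): the geometric center P_sc, mm.
#' @export
findCenter <- function(volume, normal, click, cfg = crossSectionConfig()) {
    normal <- unitv(normal)
    b <- planeBasis(normal)
    g <- seq(-cfg$gridHalfWidth, cfg$gridHalfWidth, by = cfg$gridStep)
    n <- length(g)
    uv <- cbind(rep(g, times = n), rep(g, each = n))
    pts <- matrix(click, n * n, 3L, byrow = TRUE) +
        uv[, 1] %o% b$e1 + uv[, 2] %o% b$e2
    vals <- sampleGrid(volume, pts)
    core <- matrix(vals >= cfg$Cmin & vals <= cfg$Cmax, n, n)
    ic <- (n + 1L) %/% 2L
    if (!core[ic, ic])
        stop("initialization outside vessel core")
    lab <- EBImage::bwlabel(core + 0)
    sel <- lab == lab[ic, ic]
    w <- matrix(vals, n, n)[sel]
    u <- matrix(uv[, 1], n, n)[sel]
    v <- matrix(uv[, 2], n, n)[sel]
    cu <- sum(w * u) / sum(w)
    cv <- sum(w * v) / sum(w)
    click + cu * b$e1 + cv * b$e2
}

#' Trace the vessel border in n directions
#'
#' From the geometric center, marches outward in \code{nRays} in-plane
#' directions at step \code{2 pi / nRays}, sampling the volume tricubically
#' every \code{marchStep} mm. The border along a ray is the first position
#' where the profile drops below \code{Odv} (sub-step located by linear
#' interpolation of the crossing). With neighbor detection on, a local
#' minimum followed within \code{lookAhead} mm by a rise above
#' \code{max(Mmin, valley + riseTol)} marks an adjacent vessel and the
#' border is pulled back to that valley. Rays that exhaust \code{maxMarch}
#' are flagged.
#'
#' @inheritParams findCenter
#' @param Psc geometric center from [findCenter()].
#' @return n x 3 matrix of border points with integer attribute
#'   \code{"flags"} (0 = ok, 1 = hit the march bound).
#' @export
traceBorder <- function(volume, normal, Psc, cfg = crossSectionConfig()) {
    normal <- unitv(normal)
    b <- planeBasis(normal)
    nr <- cfg$nRays
    theta <- 2 * pi * (seq_len(nr) - 1L) / nr
    r <- seq(cfg$marchStep, cfg$maxMarch, by = cfg$marchStep)
    m <- length(r)
    dirs <- cos(theta) %o% b$e1 + sin(theta) %o% b$e2     # nr x 3
    pts <- matrix(NA_real_, nr * m, 3L)
    for (i in seq_len(nr))
        pts[(i - 1L) * m + seq_len(m), ] <-
            matrix(Psc, m, 3L, byrow = TRUE) + r %o% dirs[i, ]
    vals <- matrix(sampleGrid(volume, pts), m, nr)
    lookN <- max(1L, round(cfg$lookAhead / cfg$marchStep))

    border <- matrix(NA_real_, nr, 3L)
    flags <- integer(nr)
    v0 <- sampleGrid(volume, matrix(Psc, 1L, 3L))
    for (i in seq_len(nr)) {
        v <- c(v0, vals[, i])
        rr <- c(0, r)
        drop <- which(v < cfg$Odv)[1]
        rBorder <- NA_real_
        if (cfg$neighborDetection) {
            # first qualifying valley: local minimum with a neighbor rise
            dv <- diff(v)
            mins <- which(head(dv, -1) < 0 & tail(dv, -1) >= 0) + 1L
            for (j in mins) {
                upto <- min(length(v), j + lookN)
                if (max(v[(j + 1L):upto]) >
                        max(cfg$Mmin, v[j] + cfg$riseTol)) {
                    rBorder <- rr[j]
                    break
                }
                if (!is.na(drop) && j > drop && rr[j] > rr[drop] + cfg$lookAhead)
                    break
            }
        }
        if (!is.na(drop)) {
            if (drop == 1L) {
                rDrop <- 0
            } else {
                f <- (v[drop - 1L] - cfg$Odv) / (v[drop - 1L] - v[drop])
                rDrop <- rr[drop - 1L] + f * (rr[drop] - rr[drop - 1L])
            }
            rBorder <- if (is.na(rBorder)) rDrop else min(rBorder, rDrop)
        }
        if (is.na(rBorder)) {
            rBorder <- cfg$maxMarch
            flags[i] <- 1L
            warning("ray exited sampling bounds before the vessel border")
        }
        border[i, ] <- Psc + rBorder * dirs[i, ]
    }
    attr(border, "flags") <- flags
    border
}

#' Smooth a traced border
#'
#' Replaces each border radius (distance from the geometric center) by the
#' circular moving average over \code{smoothingWindow} rays; ray directions
#' are preserved.
#'
#' @param border n x 3 border matrix from [traceBorder()].
#' @param Psc geometric center.
#' @param cfg a [crossSectionConfig()].
#' @return Smoothed n x 3 border matrix.
#' @export
smoothBorder <- function(border, Psc, cfg = crossSectionConfig()) {
    n <- nrow(border)
    w <- cfg$smoothingWindow
    if (n < w) stop("need at least smoothingWindow border points")
    offs <- border - matrix(Psc, n, 3L, byrow = TRUE)
    rad <- sqrt(rowSums(offs^2))
    dirs <- offs / rad
    h <- (w - 1L) %/% 2L
    idx <- outer(seq_len(n), -h:h, function(i, k) ((i + k - 1L) %% n) + 1L)
    radS <- rowMeans(matrix(rad[idx], n))
    out <- matrix(Psc, n, 3L, byrow = TRUE) + dirs * radS
    attr(out, "flags") <- attr(border, "flags")
    out
}

#' Diameters and area of a traced border
#'
#' Extreme diameters are the shortest and longest chords between opposite
#' border points (ray i paired with ray i + n/2); the cross-section area is
#' the closed triangle fan around the geometric center; the average diameter
#' is the diameter of the circle with that area,
#' \code{dAvg = sqrt(4 * area / pi)}.
#'
#' @param border n x 3 border matrix (n >= 8, even for chord pairing).
#' @param Psc geometric center.
#' @param normal unit plane normal (stored in the result).
#' @return A \linkS4class{CrossSection}.
#' @export
measureCrossSection <- function(border, Psc, normal = c(0, 0, 1)) {
    n <- nrow(border)
    if (n < 8L) stop("need at least 8 border points")
    half <- n %/% 2L
    chord <- vapply(seq_len(half), function(i)
        vnorm(border[i, ] - border[i + half, ]), numeric(1))
    nxt <- c(2:n, 1L)
    a <- border - matrix(Psc, n, 3L, byrow = TRUE)
    bb <- border[nxt, , drop = FALSE] - matrix(Psc, n, 3L, byrow = TRUE)
    tri <- vapply(seq_len(n), function(i)
        0.5 * vnorm(cross3(a[i, ], bb[i, ])), numeric(1))
    area <- sum(tri)
    flags <- attr(border, "flags")
    new("CrossSection", center = as.numeric(Psc), normal = unitv(normal),
        border = border, dMin = min(chord), dMax = max(chord),
        dAvg = sqrt(4 * area / pi), area = area,
        flags = if (is.null(flags)) integer(n) else flags)
}

#' Orient the measuring plane perpendicular to the vessel
#'
#' Starting from an initial direction (e.g. the tracking direction or the
#' local distance-map ridge direction), refines two tilt angles by
#' coordinate-wise golden-section search so that the measured cross-section
#' area is locally minimal; a perpendicular plane cuts the smallest section
#' of a tube.
#'
#' @param volume a \linkS4class{VascVolume}.
#' @param P point inside the vessel.
#' @param initialDirection starting normal estimate.
#' @param cfg a [crossSectionConfig()].
#' @param maxTilt search half-range per tilt angle, radians.
#' @param tol angular tolerance, radians (default ~1 degree).
#' @return Unit plane normal.
#' @export
orientPlane <- function(volume, P, initialDirection,
                        cfg = crossSectionConfig(), maxTilt = pi / 6,
                        tol = pi / 180) {
    n0 <- unitv(initialDirection)
    b <- planeBasis(n0)
    areaOf <- function(al, be) {
        nn <- unitv(rotateAbout(rotateAbout(n0, b$e1, al), b$e2, be))
        tryCatch({
            Psc <- findCenter(volume, nn, P, cfg)
            brd <- smoothBorder(traceBorder(volume, nn, Psc, cfg), Psc, cfg)
            measureCrossSection(brd, Psc, nn)@area
        }, error = function(e) Inf)
    }
    if (!is.finite(areaOf(0, 0)))
        stop("point is not inside a measurable vessel")
    al <- 0; be <- 0
    for (it in 1:2) {
        al <- optimize(function(x) areaOf(x, be), c(al - maxTilt, al + maxTilt),
                       tol = tol)$minimum
        be <- optimize(function(x) areaOf(al, x), c(be - maxTilt, be + maxTilt),
                       tol = tol)$minimum
    }
    unitv(rotateAbout(rotateAbout(n0, b$e1, al), b$e2, be))
}

#' Measure a vessel cross-section at a point
#'
#' Convenience pipeline: optional plane orientation refinement, geometric
#' center, border tracing, smoothing and measurement.
#'
#' @param volume a \linkS4class{VascVolume}.
#' @param click point inside the vessel core.
#' @param direction local vessel axis estimate (plane normal).
#' @param cfg a [crossSectionConfig()].
#' @param refineOrientation run [orientPlane()] first?
#' @return A \linkS4class{CrossSection}.
#' @export
measureVessel <- function(volume, click, direction,
                          cfg = crossSectionConfig(),
                          refineOrientation = FALSE) {
    normal <- unitv(direction)
    if (refineOrientation)
        normal <- orientPlane(volume, click, normal, cfg)
    Psc <- findCenter(volume, normal, click, cfg)
    brd <- traceBorder(volume, normal, Psc, cfg)
    brd <- smoothBorder(brd, Psc, cfg)
    measureCrossSection(brd, Psc, normal)
}
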