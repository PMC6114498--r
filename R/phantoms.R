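# Synthetic vascular phantoms: torus, helix and artificial bifurcation zones
# painted into a HU volume with a sigmoid cross-profile, plus their analytic
# ground truth.

#' Sigmoid HU profile across a vessel
#'
#' \deqn{HU(r) = C + C (1/2 - 1 / (1 + e^{-a (r - R)}))}
#' The profile equals exactly \code{C} at \code{r = R}, tends to
#' \code{1.5 C} on the vessel axis and to \code{C / 2} far outside, and is
#' monotonically non-increasing in \code{r}.
#'
#' @param r distance from the vessel axis, mm (vectorized).
#' @param C HU at the vessel boundary.
#' @param R vessel radius, mm.
#' @param a slope coefficient of the HU falloff.
#' @return HU values, same length as \code{r}.
#' @examples
#' huProfile(5, C = 150, R = 5, a = 10)   # exactly 150 at the boundary
#' huProfile(0, C = 150, R = 5, a = 10)   # ~225 on the axis
#' @export
huProfile <- function(r, C = 150, R, a = 10) {
    if (R <= 0 || a <= 0) stop("R and a must be positive")
    if (C <= 0) stop("C must be positive")
    C + C * (0.5 - 1 / (1 + exp(-a * (r - R))))
}

# Fresh background volume at the far-field value C/2 so that thresholding
# behaves as it does on painted regions.
newPhantomVolume <- function(extent = 100, spacing = 0.6, C = 150) {
    n <- as.integer(floor(extent / spacing + 1e-9)) + 1L
    VascVolume(array(C / 2, c(n, n, n)), spacing = rep(spacing, 3L),
               origin = c(0, 0, 0))
}

phantomCenter <- function(volume) {
    volume@origin + (dim(volume@data) - 1L) * volume@spacing / 2
}

#' Apply the spatial brush at one point
#'
#' Paints the sigmoid profile centered at \code{center} into the volume,
#' keeping per voxel the maximum of the current and painted value
#' (idempotent and commutative over strokes). The brush support is a cube of
#' half-width \code{support * radius} so that the sigmoid tail is captured.
#'
#' @param volume a \linkS4class{VascVolume}.
#' @param center 3-D physical point, mm.
#' @param radius local vessel radius R, mm.
#' @param C,a profile parameters, see [huProfile()].
#' @param support cube half-width as a multiple of \code{radius}.
#' @return The painted \linkS4class{VascVolume}.
#' @export
paintBrush <- function(volume, center, radius, C = 150, a = 10,
                       support = 1.5) {
    stopifnot(is(volume, "VascVolume"))
    ext <- physExtent(volume)
    if (any(center < ext[1, ]) || any(center > ext[2, ])) {
        warning("brush center outside the volume extent; volume unchanged")
        return(volume)
    }
    paintStrokes(volume, matrix(center, 1L, 3L), radius, C, a, support)
}

paintStrokes <- function(volume, centers, radius, C, a, support = 1.5) {
    if (length(radius) == 1L) radius <- rep(radius, nrow(centers))
    out <- cpp_paint_strokes(volume@data, dim(volume@data),
                             volume@spacing, volume@origin, centers, radius,
                             C, a, support)
    VascVolume(array(out, dim(volume@data)), volume@spacing, volume@origin)
}

# Stroke centers along a parametric curve at arc stride strideFrac * spacing.
curveStrokes <- function(fn, tRange, speed, spacing, strideFrac = 0.25) {
    stride <- strideFrac * spacing
    n <- max(2L, ceiling((tRange[2] - tRange[1]) * speed / stride) + 1L)
    t <- seq(tRange[1], tRange[2], length.out = n)
    t(vapply(t, fn, numeric(3)))
}

#' Generate a torus phantom with analytic ground truth
#'
#' A circular tube of diameter \code{D} swept along a circle of radius
#' \code{R1} in the central z-plane of a cubic volume, painted with the
#' sigmoid profile.
#'
#' @param D vessel diameter, mm.
#' @param R1 basal (sweep circle) radius, mm.
#' @param C,a profile parameters, see [huProfile()].
#' @param spacing voxel size, mm.
#' @param extent physical cube side, mm.
#' @return list(volume = \linkS4class{VascVolume}, truth =
#'   \linkS4class{GroundTruth}).
#' @export
makeTorus <- function(D, R1, C = 150, a = 10, spacing = 0.6, extent = 100) {
    if (2 * R1 + D >= extent)
        stop(sprintf("torus (2*R1 + D = %g mm) does not fit the %g mm volume",
                     2 * R1 + D, extent))
    vol <- newPhantomVolume(extent, spacing, C)
    ctr <- phantomCenter(vol)
    circle <- function(t) ctr + c(R1 * cos(t), R1 * sin(t), 0)
    strokes <- curveStrokes(circle, c(0, 2 * pi), R1, spacing)
    vol <- paintStrokes(vol, strokes, D / 2, C, a)
    L <- 2 * pi * R1
    truth <- new("GroundTruth", kind = "torus",
        centerline = function(s) ctr + c(R1 * cos(s / R1), R1 * sin(s / R1), 0),
        arcRange = c(0, L),
        radius = function(s) rep(D / 2, length(s)),
        distanceTo = function(p) {
            p <- if (is.matrix(p)) p else matrix(p, ncol = 3L, byrow = TRUE)
            dx <- p[, 1] - ctr[1]; dy <- p[, 2] - ctr[2]; dz <- p[, 3] - ctr[3]
            sqrt((sqrt(dx^2 + dy^2) - R1)^2 + dz^2)
        },
        curvature = 1 / R1, torsion = 0,
        geometry = list(center = ctr, D = D, R1 = R1, closed = TRUE,
            tangent = function(s) c(-sin(s / R1), cos(s / R1), 0)))
    list(volume = vol, truth = truth)
}

#' Generate a helix phantom with analytic ground truth
#'
#' The tube axis is the circular helix
#' \code{(R1 cos t, R1 sin t, b t)} with \code{b = R2 / (2 pi)}, i.e.
#' \code{R2} is the axial rise per full turn ("spiral addition"). The swept
#' parameter range is at most one turn and is clipped so the tube stays
#' inside the volume. Analytic curvature and torsion are
#' \code{R1 / (R1^2 + b^2)} and \code{b / (R1^2 + b^2)}.
#'
#' @inheritParams makeTorus
#' @param R2 axial rise per turn, mm.
#' @return list(volume, truth) as in [makeTorus()].
#' @export
makeHelix <- function(D, R1, R2, C = 150, a = 10, spacing = 0.6,
                      extent = 100) {
    if (2 * R1 + D >= extent)
        stop("helix does not fit the volume in the transverse plane")
    b <- R2 / (2 * pi)
    halfz <- extent / 2 - D / 2 - 2
    Tmax <- if (b > 0) min(pi, halfz / b) else pi
    if (Tmax <= 0) stop("helix does not fit the volume axially")
    vol <- newPhantomVolume(extent, spacing, C)
    ctr <- phantomCenter(vol)
    hx <- function(t) ctr + c(R1 * cos(t), R1 * sin(t), b * t)
    speed <- sqrt(R1^2 + b^2)
    strokes <- curveStrokes(hx, c(-Tmax, Tmax), speed, spacing)
    vol <- paintStrokes(vol, strokes, D / 2, C, a)
    L <- 2 * Tmax * speed
    t_of_s <- function(s) -Tmax + s / speed
    distFn <- function(p) {
        p <- if (is.matrix(p)) p else matrix(p, ncol = 3L, byrow = TRUE)
        apply(p, 1L, function(q) {
            f <- function(t) sqrt(sum((hx(t) - q)^2))
            tg <- seq(-Tmax, Tmax, length.out = 400L)
            d <- vapply(tg, f, numeric(1))
            i <- which.min(d)
            lo <- tg[max(1L, i - 1L)]; hi <- tg[min(length(tg), i + 1L)]
            optimize(f, c(lo, hi))$objective
        })
    }
    truth <- new("GroundTruth", kind = "helix",
        centerline = function(s) hx(t_of_s(s)),
        arcRange = c(0, L),
        radius = function(s) rep(D / 2, length(s)),
        distanceTo = distFn,
        curvature = R1 / (R1^2 + b^2), torsion = b / (R1^2 + b^2),
        geometry = list(center = ctr, D = D, R1 = R1, R2 = R2, b = b,
            Tmax = Tmax, closed = FALSE,
            tangent = function(s) {
                t <- t_of_s(s)
                c(-R1 * sin(t), R1 * cos(t), b) / speed
            }))
    list(volume = vol, truth = truth)
}

#' Build a phantom from a PhantomSpec
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param spacing,extent volume geometry, mm.
#' @return list(volume, truth).
#' @export
makePhantom <- function(spec, spacing = 0.6, extent = 100) {
    stopifnot(is(spec, "PhantomSpec"))
    if (spec@kind == "torus")
        makeTorus(spec@D, spec@R1, spec@Cb, spec@a, spacing, extent)
    else
        makeHelix(spec@D, spec@R1, spec@R2, spec@Cb, spec@a, spacing, extent)
}

#' Enumerate a Cartesian phantom parameter grid with the rejection rule
#'
#' Builds all (D, R1[, R2]) combinations and removes the self-overlapping
#' ones (R1 < 2D, and for the helix R2 < 2D). Ordering is lexicographic by
#' D, then R1, then R2. The raw (pre-rejection) combination count is
#' attached as attribute \code{"rawCount"}.
#'
#' @param kind "torus" or "helix".
#' @param D,R1,R2 numeric vectors of grid values (R2 ignored for torus).
#' @param C,a profile parameters for the resulting specs.
#' @return List of \linkS4class{PhantomSpec}.
#' @export
enumerateModelGrid <- function(kind, D, R1, R2 = NULL, C = 150, a = 10) {
    D <- sort(unique(D)); R1 <- sort(unique(R1))
    if (kind == "helix") {
        if (is.null(R2)) stop("helix grid requires R2 values")
        R2 <- sort(unique(R2))
        g <- expand.grid(R2 = R2, R1 = R1, D = D)[, c("D", "R1", "R2")]
    } else {
        g <- expand.grid(R1 = R1, D = D)[, c("D", "R1")]
        g$R2 <- rep(NA_real_, nrow(g))
    }
    raw <- nrow(g)
    keep <- g$R1 >= 2 * g$D
    if (kind == "helix") keep <- keep & g$R2 >= 2 * g$D
    g <- g[keep, , drop = FALSE]
    specs <- lapply(seq_len(nrow(g)), function(i)
        PhantomSpec(kind, g$D[i], g$R1[i], g$R2[i], C, a))
    attr(specs, "rawCount") <- raw
    specs
}

#' Default validation parameter grids
#'
#' The full grids used for the diameter-accuracy experiment: torus D 1-5 mm
#' step 0.25, R1 5-30 mm step 1; helix additionally R2 5-9 mm step 1 with
#' D starting at 1.5 mm. \code{stride} thins every dimension by taking each
#' stride-th value, for scaled-down runs.
#'
#' @param kind "torus" or "helix".
#' @param stride integer >= 1 grid thinning factor.
#' @return List of \linkS4class{PhantomSpec} (see [enumerateModelGrid()]).
#' @export
diameterValidationGrid <- function(kind, stride = 1L) {
    thin <- function(v) v[seq(1L, length(v), by = stride)]
    if (kind == "torus")
        enumerateModelGrid("torus", thin(seq(1, 5, 0.25)), thin(seq(5, 30, 1)))
    else
        enumerateModelGrid("helix", thin(seq(1.5, 4, 0.25)), thin(seq(5, 30, 1)),
                           thin(seq(5, 9, 1)))
}

#' Sample random ABZ parameter sets
#'
#' Each field is drawn independently and uniformly within its range
#' (the distribution inside the anatomical ranges is a package choice).
#'
#' @param n number of parameter sets.
#' @param ranges named list of c(min, max) ranges, see [abzRanges()].
#' @param seed optional integer seed for reproducibility.
#' @return List of \linkS4class{ABZParams}.
#' @export
sampleABZ <- function(n, ranges = abzRanges(), seed = NULL) {
    stopifnot(n > 0)
    withSeed(seed, {
        lapply(seq_len(n), function(i) {
            v <- vapply(ranges, function(r) runif(1, r[1], r[2]), numeric(1))
            new("ABZParams", A1 = v[["A1"]], A2 = v[["A2"]],
                A1pl = v[["A1pl"]], A2pl = v[["A2pl"]], wAn = v[["wAn"]],
                DT = v[["DT"]], D1 = v[["D1"]], D2 = v[["D2"]],
                Dan = v[["Dan"]])
        })
    })
}

#' Generate an artificial bifurcation zone phantom
#'
#' A straight cylindrical trunk (diameter DT, length 20 mm) along +z ends at
#' the apex, where two straight branches (diameters D1, D2, length 15 mm)
#' deviate from the trunk axis by A1 and A2 degrees on opposite sides of the
#' nominal division plane (y = const), each additionally tilted out of that
#' plane by A1pl, A2pl degrees. Optionally a spherical aneurysm of diameter
#' Dan sits past the apex on the trunk axis. Ground-truth angles and
#' coplanarity indices are computed from the construction direction vectors;
#' the true division-plane normal is the normal of the plane spanned by the
#' two branch directions.
#'
#' @param params an \linkS4class{ABZParams}.
#' @param includeAneurysm paint the aneurysm sphere?
#' @param C,a profile parameters, see [huProfile()].
#' @param spacing,extent volume geometry, mm.
#' @return list(volume, truth).
#' @export
makeBifurcation <- function(params, includeAneurysm = TRUE, C = 150, a = 10,
                            spacing = 0.6, extent = 100) {
    stopifnot(is(params, "ABZParams"))
    trunkLen <- 20; branchLen <- 15
    deg <- pi / 180
    tdir <- c(0, 0, 1)
    branchDir <- function(A, Apl, side) {
        c(side * sin(A * deg) * cos(Apl * deg), sin(Apl * deg),
          cos(A * deg) * cos(Apl * deg))
    }
    u1 <- branchDir(params@A1, params@A1pl, +1)
    u2 <- branchDir(params@A2, params@A2pl, -1)

    vol <- newPhantomVolume(extent, spacing, C)
    apex <- phantomCenter(vol)
    trunkStart <- apex - trunkLen * tdir
    seg <- function(p0, u, len) function(t) p0 + t * len * u
    vol <- paintStrokes(vol,
        curveStrokes(seg(trunkStart, tdir, trunkLen), c(0, 1), trunkLen, spacing),
        params@DT / 2, C, a)
    vol <- paintStrokes(vol,
        curveStrokes(seg(apex, u1, branchLen), c(0, 1), branchLen, spacing),
        params@D1 / 2, C, a)
    vol <- paintStrokes(vol,
        curveStrokes(seg(apex, u2, branchLen), c(0, 1), branchLen, spacing),
        params@D2 / 2, C, a)
    if (includeAneurysm && params@Dan > 0)
        vol <- paintStrokes(vol,
            matrix(apex + (params@Dan / 2) * tdir, 1L, 3L),
            params@Dan / 2, C, a)

    dpn <- unitv(cross3(u1, u2))
    truth <- new("GroundTruth", kind = "abz",
        centerline = function(s) trunkStart + s * tdir,
        arcRange = c(0, trunkLen),
        radius = function(s) rep(params@DT / 2, length(s)),
        distanceTo = function(p) {
            p <- if (is.matrix(p)) p else matrix(p, ncol = 3L, byrow = TRUE)
            segs <- list(rbind(trunkStart, apex),
                         rbind(apex, apex + branchLen * u1),
                         rbind(apex, apex + branchLen * u2))
            apply(p, 1L, function(q)
                min(vapply(segs, function(sg) pointPolylineDistance(q, sg),
                           numeric(1))))
        },
        curvature = NA_real_, torsion = NA_real_,
        geometry = list(
            apex = apex, trunkStart = trunkStart, trunkDir = tdir,
            branchDirs = list(u1, u2),
            branchEnds = list(apex + branchLen * u1, apex + branchLen * u2),
            diameters = c(DT = params@DT, D1 = params@D1, D2 = params@D2,
                          Dan = params@Dan),
            includeAneurysm = includeAneurysm,
            trueBA = angleBetween(u1, u2),
            trueVA = c(angleBetween(tdir, u1), angleBetween(tdir, u2)),
            trueDPN = dpn,
            trueCoI = c(T = coplanarityIndex(tdir, dpn),
                        b1 = coplanarityIndex(u1, dpn),
                        b2 = coplanarityIndex(u2, dpn)),
            dominant = if (params@D2 > params@D1) 2L else 1L))
    list(volume = vol, truth = truth)
}

#' Write ground truth as a JSON sidecar
#'
#' Serializes centerline samples at a fixed arc step plus any true angles.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param path output .json path.
#' @param arcStep sampling step along the arc, mm.
#' @export
writeGroundTruth <- function(truth, path, arcStep = 0.1) {
    s <- seq(truth@arcRange[1], truth@arcRange[2], by = arcStep)
    pts <- t(vapply(s, truth@centerline, numeric(3)))
    out <- list(kind = truth@kind, arcRange = truth@arcRange,
                samples = data.frame(s = s, x = pts[, 1], y = pts[, 2],
                                     z = pts[, 3], radius = truth@radius(s)))
    g <- truth@geometry
    for (nm in c("trueBA", "trueVA", "trueCoI", "trueDPN"))
        if (!is.null(g[[nm]])) out[[nm]] <- g[[nm]]
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
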