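# Division (bifurcation) zone construction: split point, Tr/Br points,
# division plane, branching/vessel angles and coplanarity indices.

#' Division-zone configuration
#'
#' @param d split-distance threshold, mm: a curve point belongs to the
#'   common zone while its minimal distance to the other curve is below
#'   \code{d} (default 0.2 mm, the auxiliary volume resolution).
#' @param pointSpacingFactor arc spacing between consecutive Tr/Br points,
#'   in multiples of the local radius. The default 3 clears the junction
#'   blend: near a division the vessel surfaces merge over roughly
#'   \code{(r_trunk + r_branch) / sin(VA)}, i.e. 2-3 radii along each
#'   vessel, and direction vectors sampled inside that blend do not reflect
#'   the vessel axes.
#' @param nPoints points placed per vessel (>= 2; points 0 and 1 define the
#'   direction vectors).
#' @return Named list of validated settings.
#' @export
zoneConfig <- function(d = 0.2, pointSpacingFactor = 3.0, nPoints = 4L) {
    if (d <= 0) stop("d must be positive")
    if (nPoints < 2L) stop("nPoints must be >= 2")
    list(d = d, pointSpacingFactor = pointSpacingFactor,
         nPoints = as.integer(nPoints))
}

#' Find the split point of two centerlines
#'
#' For each curve, the last point (in flow order) whose minimal distance to
#' the other curve is below \code{d}; the split point T0 is the
#' component-wise midpoint of the two points found (the geometric middle; a
#' literal coordinate-wise geometric mean would not be translation
#' invariant).
#'
#' @param curveA,curveB \linkS4class{Centerline}s that share a common stem.
#' @param cfg a [zoneConfig()].
#' @return list(T0, indexA, indexB, arcA, arcB): the split point, the
#'   indices of the last tracked vertex inside the common zone on each
#'   curve, and the interpolated arc positions of the zone end.
#' @export
findSplitPoint <- function(curveA, curveB, cfg = zoneConfig()) {
    A <- curveA@points; B <- curveB@points
    if (nrow(A) == nrow(B) && max(abs(A - B)) < 1e-12)
        stop("degenerate division: curves are identical")
    # the split is located on the continuous curves, not just on tracked
    # vertices: resample both polylines densely before the distance test
    dsA <- densePolyline(A, curveA@cumLength, cfg$d / 2)
    dsB <- densePolyline(B, curveB@cumLength, cfg$d / 2)
    dA <- vapply(seq_len(nrow(dsA$points)), function(i)
        pointPolylineDistance(dsA$points[i, ], B), numeric(1))
    dB <- vapply(seq_len(nrow(dsB$points)), function(i)
        pointPolylineDistance(dsB$points[i, ], A), numeric(1))
    ia <- which(dA < cfg$d)
    ib <- which(dB < cfg$d)
    if (length(ia) == 0L || length(ib) == 0L)
        stop("no division: curves never approach within d")
    ia <- max(ia); ib <- max(ib)
    arcA <- dsA$arc[ia]; arcB <- dsB$arc[ib]
    pA <- dsA$points[ia, ]; pB <- dsB$points[ib, ]
    list(T0 = (pA + pB) / 2,
         indexA = max(1L, findInterval(arcA, curveA@cumLength)),
         indexB = max(1L, findInterval(arcB, curveB@cumLength)),
         arcA = arcA, arcB = arcB)
}

#' Refine two tracked curves around their division
#'
#' Crawl-rate steps are proportional to the local inscribed radius, which
#' inflates in the junction blend, so tracked vertices can cut the corner of
#' a division by up to one step length. This pass re-tracks a neighborhood
#' of the preliminary split point on both curves with a small capped step
#' (default 0.25 mm), so that the curves follow their ridges through the
#' junction and the split point is resolved at the d scale.
#'
#' @param dmap the \linkS4class{DistanceMap} the curves were tracked on.
#' @param curveA,curveB tracked \linkS4class{Centerline}s.
#' @param cfg a [zoneConfig()].
#' @param trackCfg the [trackingConfig()] used for tracking.
#' @param fineStep step cap for the refinement crawl, mm.
#' @param back,forward extent of the re-tracked neighborhood around the
#'   preliminary split, mm.
#' @return list(curveA, curveB): the refined curves.
#' @export
refineDivision <- function(dmap, curveA, curveB, cfg = zoneConfig(),
                           trackCfg = trackingConfig(), fineStep = 0.25,
                           back = 4, forward = 6) {
    prelim <- findSplitPoint(curveA, curveB, cfg)
    fineCfg <- trackCfg
    fineCfg$maxStep <- fineStep
    fineCfg$stopDistance <- 3 * fineStep
    fineCfg$maxSteps <- max(50L, ceiling(3 * (back + forward) / fineStep))
    refine <- function(cl, arc) {
        total <- cl@cumLength[length(cl@cumLength)]
        a0 <- max(0, arc - back)
        a1 <- min(total, arc + forward)
        if (a1 - a0 < 2 * fineStep) return(cl)
        rad <- cl@radius
        at0 <- polylineAt(cl@points, cl@cumLength, a0, rad)
        at1 <- polylineAt(cl@points, cl@cumLength, a1, rad)
        # re-track against the flow (distal to proximal): entering the
        # trunk from a branch is a merge, so no branch choice arises
        tangent <- at1$p - polylineAt(cl@points, cl@cumLength,
                                      max(0, a1 - 0.5))
        fine <- tryCatch(
            trackCenterline(dmap, at1$p, at0$p, fineCfg,
                            initDirection = -tangent),
            error = function(e) NULL)
        if (is.null(fine) || !fine@converged) return(cl)
        fine <- reverseCenterline(fine)
        pre <- cl@cumLength < a0 - 1e-9
        post <- cl@cumLength > a1 + 1e-9
        Centerline(rbind(cl@points[pre, , drop = FALSE], fine@points,
                         cl@points[post, , drop = FALSE]),
                   radius = c(rad[pre], fine@radius, rad[post]),
                   curveType = cl@curveType, converged = cl@converged)
    }
    list(curveA = refine(curveA, prelim$arcA),
         curveB = refine(curveB, prelim$arcB))
}

#' Split two tracked curves into trunk and branch pieces
#'
#' Uses [findSplitPoint()] to cut the shared stem: the trunk piece is the
#' first curve up to its last common point, and each branch piece starts at
#' the first point past the common zone.
#'
#' @param curveA,curveB \linkS4class{Centerline}s tracked from a common
#'   start to the two branch endpoints.
#' @param cfg a [zoneConfig()].
#' @return list(trunk, branch1, branch2, T0) of \linkS4class{Centerline}s
#'   and the split point.
#' @export
splitDivision <- function(curveA, curveB, cfg = zoneConfig()) {
    sp <- findSplitPoint(curveA, curveB, cfg)
    cutAt <- function(cl, arc) {
        rad <- cl@radius
        if (all(is.na(rad))) rad <- rep(NA_real_, length(cl@cumLength))
        at <- polylineAt(cl@points, cl@cumLength, arc, rad)
        pre <- cl@cumLength < arc - 1e-9
        post <- cl@cumLength > arc + 1e-9
        list(head = Centerline(rbind(cl@points[pre, , drop = FALSE], at$p),
                               radius = c(rad[pre], at$r),
                               curveType = cl@curveType),
             tail = Centerline(rbind(at$p, cl@points[post, , drop = FALSE]),
                               radius = c(at$r, rad[post]),
                               curveType = cl@curveType))
    }
    cutA <- cutAt(curveA, sp$arcA)
    cutB <- cutAt(curveB, sp$arcB)
    list(trunk = cutA$head, branch1 = cutA$tail, branch2 = cutB$tail,
         T0 = sp$T0)
}

# Place `n` points along a polyline starting at arc position s0, marching by
# pointSpacingFactor * local radius, in the direction of increasing (dir=+1)
# or decreasing (dir=-1) arc length. Returns points and radii.
placeZonePoints <- function(points, radius, s0, n, factor, dir = 1) {
    cum <- arcLength(points)
    rad <- radius
    if (all(is.na(rad))) rad <- rep(mean(diff(cum)), length(cum))
    rad[is.na(rad)] <- mean(rad, na.rm = TRUE)
    out <- matrix(NA_real_, n, 3L)
    rr <- numeric(n)
    s <- s0
    total <- cum[length(cum)]
    for (i in seq_len(n)) {
        s <- max(0, min(total, s))
        at <- polylineAt(points, cum, s, rad)
        out[i, ] <- at$p
        rr[i] <- at$r
        s <- s + dir * factor * max(at$r, 1e-6)
        if ((dir > 0 && s > total + 1e-9) || (dir < 0 && s < -1e-9)) {
            if (i < n) {
                warning("centerline too short for requested zone points; truncating")
                out <- out[seq_len(i), , drop = FALSE]
                rr <- rr[seq_len(i)]
                break
            }
        }
    }
    list(points = out, radius = rr)
}

#' Build a bifurcation zone from trunk and branch centerlines
#'
#' Tr points start at the split point T0 and march up the trunk against the
#' flow; each branch's point 0 is its first point past the common zone
#' (minimal distance to the other branch >= d), with subsequent points
#' marching with the flow. Consecutive points are spaced by
#' \code{pointSpacingFactor} times the local radius. The division plane
#' passes through the three 0-points with its normal signed toward the
#' trunk flow direction; angles and coplanarity indices are computed from
#' the vessel directional vectors.
#'
#' @param trunk,branch1,branch2 \linkS4class{Centerline} pieces from
#'   [splitDivision()] (trunk in flow order ending at the split; branches
#'   starting at the split).
#' @param T0 split point (defaults to the last trunk point).
#' @param cfg a [zoneConfig()].
#' @return A \linkS4class{BifurcationZone}.
#' @export
buildZone <- function(trunk, branch1, branch2, T0 = NULL,
                      cfg = zoneConfig()) {
    if (is.null(T0)) T0 <- trunk@points[nrow(trunk@points), ]
    fac <- cfg$pointSpacingFactor
    n <- cfg$nPoints

    # Tr: from the trunk end (split) backwards. When the shared ridge run
    # extends past the anatomical trunk into the junction blend, the trunk
    # piece ends with a kink: its tail bends away from the straight
    # proximal run. Tr_0 is pulled back to the most distal point whose
    # local direction still agrees with the proximal trunk direction; the
    # stored split point T0 is unaffected.
    cumT <- trunk@cumLength
    trStart <- cumT[length(cumT)]
    if (length(cumT) > 3L && trStart > 4) {
        ds <- densePolyline(trunk@points, cumT, 0.25)
        m <- nrow(ds$points)
        w <- max(2L, round(1 / 0.25))   # ~1 mm direction window
        refDir <- unitv(ds$points[min(m, ceiling(m / 2)), ] - ds$points[1, ])
        kink <- trStart
        for (i in seq(m, w + 1L)) {
            d1 <- ds$points[i, ] - ds$points[i - w, ]
            if (vnorm(d1) > 1e-9 &&
                angleBetween(d1, refDir) < 10) {
                kink <- ds$arc[i]
                break
            }
        }
        trStart <- max(min(trStart, kink), trStart - 8)
    }
    tr <- placeZonePoints(trunk@points, trunk@radius, trStart, n, fac,
                          dir = -1)
    if (abs(trStart - cumT[length(cumT)]) < 1e-9) tr$points[1, ] <- T0

    # Point 0 of a branch: first point past the common zone. Two conditions:
    # the point clears the whole opposite curve (shared trunk run included)
    # by d, and its local inscribed radius has settled to the branch's own
    # caliber — while the inscribed ball is still inflated by the junction
    # blend, the point does not yet lie on the branch proper. Located on the
    # densely resampled curve.
    br0 <- function(br, otherPts) {
        ds <- densePolyline(br@points, br@cumLength, cfg$d / 2)
        dmin <- vapply(seq_len(nrow(ds$points)), function(i)
            pointPolylineDistance(ds$points[i, ], otherPts), numeric(1))
        i0 <- which(dmin >= cfg$d)[1]
        if (is.na(i0)) i0 <- length(ds$arc)
        rad <- br@radius
        if (!all(is.na(rad))) {
            radD <- approx(br@cumLength, rad, xout = ds$arc, rule = 2)$y
            total <- ds$arc[length(ds$arc)]
            rRef <- median(radD[ds$arc >= total / 2], na.rm = TRUE)
            iMax <- which(ds$arc <= ds$arc[i0] + 5 * rRef)
            iMax <- iMax[length(iMax)]
            settled <- which(radD <= 1.15 * rRef & seq_along(radD) >= i0)
            settled <- settled[settled <= iMax]
            if (length(settled)) i0 <- settled[1]
        }
        ds$arc[i0]
    }
    b1 <- placeZonePoints(branch1@points, branch1@radius,
                          br0(branch1, rbind(trunk@points, branch2@points)),
                          n, fac, dir = +1)
    b2 <- placeZonePoints(branch2@points, branch2@radius,
                          br0(branch2, rbind(trunk@points, branch1@points)),
                          n, fac, dir = +1)

    vdvT <- unitv(tr$points[1, ] - tr$points[2, ])    # Tr1 -> Tr0, downstream
    vdv1 <- unitv(b1$points[2, ] - b1$points[1, ])    # Br0 -> Br1
    vdv2 <- unitv(b2$points[2, ] - b2$points[1, ])
    dp <- divisionPlane(tr$points[1, ], b1$points[1, ], b2$points[1, ],
                        flowDirection = vdvT)

    dominant <- if (mean(b2$radius) > mean(b1$radius)) 2L else 1L
    new("BifurcationZone", T0 = as.numeric(T0), Tr = tr$points,
        Br1 = b1$points, Br2 = b2$points, TrRadius = tr$radius,
        Br1Radius = b1$radius, Br2Radius = b2$radius,
        DPoint = dp$point, DPN = dp$normal,
        VDVT = vdvT, VDV1 = vdv1, VDV2 = vdv2,
        BA = angleBetween(vdv1, vdv2),
        VA1 = angleBetween(vdvT, vdv1), VA2 = angleBetween(vdvT, vdv2),
        CoIT = coplanarityIndex(vdvT, dp$normal),
        CoI1 = coplanarityIndex(vdv1, dp$normal),
        CoI2 = coplanarityIndex(vdv2, dp$normal),
        dominant = dominant)
}

#' Division plane through the three zone 0-points
#'
#' @param p0,p1,p2 the trunk and branch 0-points (or a
#'   \linkS4class{BifurcationZone} as the single first argument).
#' @param flowDirection optional trunk flow direction fixing the normal
#'   sign (positive component along it when not perpendicular).
#' @return list(point, normal): a point on the plane and its unit normal.
#' @export
divisionPlane <- function(p0, p1 = NULL, p2 = NULL, flowDirection = NULL) {
    if (is(p0, "BifurcationZone")) {
        z <- p0
        return(divisionPlane(z@Tr[1, ], z@Br1[1, ], z@Br2[1, ],
                             flowDirection = z@VDVT))
    }
    v1 <- p1 - p0
    v2 <- p2 - p0
    nrm <- cross3(v1, v2)
    if (vnorm(nrm) < 1e-9 * max(vnorm(v1) * vnorm(v2), 1e-12))
        stop("degenerate plane: the three zone 0-points are collinear")
    nrm <- unitv(nrm)
    if (!is.null(flowDirection) && sum(nrm * flowDirection) < 0) nrm <- -nrm
    list(point = p0, normal = nrm)
}

#' Branching and vessel angles of a zone
#'
#' BA is the angle between the two branch directional vectors; VA_i between
#' the trunk (downstream) and branch i directional vectors.
#'
#' @param zone a \linkS4class{BifurcationZone}.
#' @return Named numeric: BA, VA1, VA2 in degrees.
#' @export
zoneAngles <- function(zone) {
    c(BA = angleBetween(zone@VDV1, zone@VDV2),
      VA1 = angleBetween(zone@VDVT, zone@VDV1),
      VA2 = angleBetween(zone@VDVT, zone@VDV2))
}

#' Coplanarity index of a vessel direction and the division-plane normal
#'
#' \deqn{CoI = 1 - angle(VDV, DPN) / (pi / 2)}
#' with the angle folded to the acute range [0, pi/2]. A vessel parallel to
#' the plane normal (perpendicular to the division plane) scores 1; a
#' vessel lying in the division plane scores 0. \code{convention =
#' "in-plane"} returns the complement (1 for a vessel lying in the plane),
#' exposed because both conventions appear in morphometric practice.
#'
#' @param vdv vessel directional vector.
#' @param dpn division-plane normal.
#' @param convention "normal" (literal definition above) or "in-plane".
#' @return CoI in [0, 1].
#' @export
coplanarityIndex <- function(vdv, dpn, convention = c("normal", "in-plane")) {
    convention <- match.arg(convention)
    if (vnorm(vdv) == 0 || vnorm(dpn) == 0) stop("zero-length vector")
    ang <- angleBetween(vdv, dpn) * pi / 180
    if (ang > pi / 2) ang <- pi - ang
    coi <- 1 - ang / (pi / 2)
    if (convention == "in-plane") 1 - coi else coi
}

#' Select the true division among candidate zones
#'
#' When one of the curves is a curve to an aneurysm sac (type 1), the zone
#' whose split point lies furthest from the trunk origin describes the
#' departure of the aneurysm dome from its parent vessel; it is flagged and
#' the remaining (non-aneurysm) zone is returned as the actual division.
#'
#' @param zones list of \linkS4class{BifurcationZone}.
#' @param trunkOrigin origin of the trunk, mm.
#' @param curveTypes list of integer pairs: the curve-type labels of the two
#'   curves forming each zone (1 = aneurysm curve).
#' @return list(division, aneurysmStem): the selected zone and the
#'   aneurysm-departure zone (NULL when no aneurysm curve is present).
#' @export
selectTrueDivision <- function(zones, trunkOrigin, curveTypes) {
    if (length(zones) == 0L) stop("no zones")
    stopifnot(length(curveTypes) == length(zones))
    dist <- vapply(zones, function(z) vnorm(z@T0 - trunkOrigin), numeric(1))
    hasAn <- vapply(curveTypes, function(tt) any(tt == 1L, na.rm = TRUE),
                    logical(1))
    if (!any(hasAn)) {
        return(list(division = zones[[which.max(dist)]], aneurysmStem = NULL))
    }
    if (all(hasAn)) stop("no non-aneurysm division: all curves are type 1")
    anIdx <- which(hasAn)[which.max(dist[hasAn])]
    divIdx <- which(!hasAn)[which.max(dist[!hasAn])]
    list(division = zones[[divIdx]], aneurysmStem = zones[[anIdx]])
}

#' Zone report as a one-row data frame
#'
#' Column names follow the conventional bifurcation-morphometry variables:
#' branching angle, dominant/non-dominant vessel angles and coplanarity
#' indices, trunk coplanarity and the split-point coordinates.
#'
#' @param zone a \linkS4class{BifurcationZone}.
#' @return data.frame with one row.
#' @export
zoneReport <- function(zone) {
    dom <- zone@dominant
    va <- c(zone@VA1, zone@VA2)
    coi <- c(zone@CoI1, zone@CoI2)
    data.frame(BA = zone@BA, VA_dom = va[dom], VA_ndom = va[3L - dom],
               CoI_dom = coi[dom], CoI_ndom = coi[3L - dom],
               CoI_T = zone@CoIT, T0_x = zone@T0[1], T0_y = zone@T0[2],
               T0_z = zone@T0[3], dominant = dom)
}
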