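# Centerline tracking: crawling over local in-plane maxima of the distance
# map, arc length bookkeeping and tree topology labels.

#' Centerline tracking configuration
#'
#' @param f crawl rate: each step advances by \code{f} times the local
#'   distance-map value (the local inscribed-ball radius). Typical values
#'   lie in [0.5, 1]; larger values risk jumping between abutting vessels,
#'   smaller ones produce rough curves, so a warning is raised outside the
#'   range.
#' @param dA half-aperture of the forward search cone, radians: the
#'   direction may change by at most \code{dA} per step (the in-plane
#'   search disc is always additionally capped by the local radius). The
#'   default 3/2 pi leaves the turn effectively unconstrained within the
#'   vessel; 3/(2 pi) (~27 degrees) is the conservative alternative
#'   reading.
#' @param stopDistance minimal stop radius around the endpoint, mm (the
#'   effective stop radius is \code{max(stopDistance, local radius)}).
#' @param maxSteps step budget before tracking is abandoned.
#' @param maxStep upper cap on the step length, mm (Inf by default; small
#'   values are used when re-tracking a division neighborhood at fine
#'   resolution).
#' @return Named list of validated settings.
#' @export
trackingConfig <- function(f = 0.5, dA = 1.5 * pi, stopDistance = 0.4,
                           maxSteps = 400L, maxStep = Inf) {
    if (f <= 0) stop("crawl rate f must be positive")
    if (f < 0.5 || f > 1)
        warning(sprintf(
            "crawl rate f = %g outside [0.5, 1]: rough curves (low f) or transitions between abutting vessels (high f) become likely", f))
    if (maxSteps <= 0) stop("maxSteps must be positive")
    list(f = f, dA = dA, stopDistance = stopDistance,
         maxSteps = as.integer(maxSteps), maxStep = maxStep)
}

# Maximize the distance map within the plane through `center` perpendicular
# to `normal`, restricted to a disc of radius rmax. Deterministic pattern
# (compass) search on a shrinking 3x3 stencil with batched sampling; robust
# on the non-smooth cone ridges of the distance map. Converges to ~1e-3 mm.
planeMaximum <- function(dmap, center, normal, rmax, init = c(0, 0)) {
    b <- planeBasis(normal)
    stencil <- cbind(c(-1, 0, 1, -1, 0, 1, -1, 0, 1),
                     c(-1, -1, -1, 0, 0, 0, 1, 1, 1))
    x <- init
    h <- max(rmax / 2, 1e-3)
    val <- -Inf
    while (h > 5e-4) {
        cand <- sweep(stencil * h, 2L, x, "+")
        rr <- sqrt(rowSums(cand^2))
        pts <- matrix(center, 9L, 3L, byrow = TRUE) +
            cand[, 1] %o% b$e1 + cand[, 2] %o% b$e2
        v <- sampleGrid(dmap, pts)
        v[rr > rmax] <- -Inf
        i <- which.max(v)
        if (v[i] > val + 1e-12 && i != 5L) {
            x <- cand[i, ]
            val <- v[i]
        } else {
            val <- max(val, v[5L])
            h <- h / 2
        }
    }
    list(point = center + x[1] * b$e1 + x[2] * b$e2, value = val)
}

#' One crawl step along the distance-map ridge
#'
#' The step length is \code{distance * f} where \code{distance} is the local
#' distance-map value at \code{P}. The next point is the local maximum of
#' the distance map within the cross-sectional plane perpendicular to the
#' travel direction at that distance ahead, searched inside the forward cone
#' of half-aperture \code{dA}. An optional target biases the in-plane search
#' start (not the maximization itself) so that the desired branch is chosen
#' at a fork.
#'
#' @param dmap a \linkS4class{DistanceMap}.
#' @param P current position, mm.
#' @param direction current unit travel direction.
#' @param cfg a [trackingConfig()].
#' @param target optional endpoint used to bias the search start.
#' @return list(point, direction, radius): the next position, the new unit
#'   direction and the distance-map value at the next position.
#' @export
crawlStep <- function(dmap, P, direction, cfg = trackingConfig(),
                      target = NULL) {
    direction <- unitv(direction)
    M <- sampleGrid(dmap, P)
    if (M <= 0) stop("left vessel: distance map is zero at the current point")
    step <- min(M * cfg$f, cfg$maxStep)
    Q <- P + step * direction
    # forward cone of half-aperture dA, additionally capped by the local
    # inscribed radius so the search cannot leave the current vessel
    rmax <- min(step * tan(min(cfg$dA, 1.2)), M)
    init <- c(0, 0)
    if (!is.null(target)) {
        b <- planeBasis(direction)
        e <- target - P
        ip <- c(sum(e * b$e1), sum(e * b$e2))
        nip <- sqrt(sum(ip^2))
        if (nip > 1e-9) {
            # start the ascent slightly toward the target's side of the plane
            init <- ip / nip * min(0.5 * rmax, nip)
        }
    }
    mx <- planeMaximum(dmap, Q, direction, rmax, init)
    if (mx$value <= 0)
        stop("left vessel: no positive in-plane distance-map maximum")
    list(point = mx$point, direction = unitv(mx$point - P),
         radius = sampleGrid(dmap, mx$point))
}

# Principal axis of the local foreground within a ball of radius `r` around
# P, signed toward `toward`.
seedDirection <- function(dmap, P, r, toward) {
    d <- dim(dmap@data)
    i0 <- pmax(1L, floor((P - r - dmap@origin) / dmap@spacing) + 1L)
    i1 <- pmin(d, ceiling((P + r - dmap@origin) / dmap@spacing) + 1L)
    ii <- lapply(1:3, function(k) seq.int(i0[k], i1[k]))
    sub <- dmap@data[ii[[1]], ii[[2]], ii[[3]], drop = FALSE]
    idx <- which(sub > 0, arr.ind = TRUE)
    if (nrow(idx) < 4L) return(unitv(toward - P))
    pts <- sweep(idx - 1, 2L, i0 - 1L, "+")
    pts <- sweep(sweep(pts, 2L, dmap@spacing, "*"), 2L, dmap@origin, "+")
    keep <- rowSums(sweep(pts, 2L, P, "-")^2) <= r^2
    if (sum(keep) < 4L) return(unitv(toward - P))
    pts <- pts[keep, , drop = FALSE]
    v <- eigen(cov(pts), symmetric = TRUE)$vectors[, 1]
    if (sum(v * (toward - P)) < 0) v <- -v
    unitv(v)
}

#' Track a centerline between two points
#'
#' Crawls from \code{start} toward \code{end} over the local in-plane maxima
#' of the distance map. The seed direction is the principal axis of the
#' local foreground (signed toward the endpoint) unless given explicitly;
#' the start point itself is refined to the in-plane distance-map maximum.
#' Tracking stops when the current point is within
#' \code{max(local radius, stopDistance)} of the endpoint; if the step
#' budget is exhausted first, the partial curve is returned with a warning
#' and \code{converged = FALSE}.
#'
#' @param dmap a \linkS4class{DistanceMap}.
#' @param start,end points inside the vessel, mm.
#' @param cfg a [trackingConfig()].
#' @param initDirection optional unit seed direction.
#' @return A \linkS4class{Centerline} with per-point radii (distance-map
#'   values) and cumulative arc length.
#' @export
trackCenterline <- function(dmap, start, end, cfg = trackingConfig(),
                            initDirection = NULL) {
    M0 <- sampleGrid(dmap, start)
    if (M0 <= 0) stop("start point is outside the vessel")
    if (sampleGrid(dmap, end) <= 0) stop("end point is outside the vessel")
    if (vnorm(end - start) < 1e-12) {
        return(Centerline(matrix(start, 1L, 3L), radius = M0))
    }
    dir <- if (is.null(initDirection))
        seedDirection(dmap, start, 3 * M0, end) else unitv(initDirection)
    # refine the seed onto the ridge in its own cross-sectional plane
    sref <- planeMaximum(dmap, start, dir, max(M0, 2 * max(dmap@spacing)))
    P <- sref$point
    R <- sref$value
    pts <- list(P)
    rad <- c(R)
    converged <- FALSE
    for (k in seq_len(cfg$maxSteps)) {
        stopR <- max(cfg$stopDistance, min(R * cfg$f, cfg$maxStep))
        if (vnorm(end - P) <= stopR) {
            converged <- TRUE
            break
        }
        st <- tryCatch(crawlStep(dmap, P, dir, cfg, target = end),
                       error = function(e) NULL)
        if (is.null(st)) break
        # reject stalls (numerically identical points)
        if (vnorm(st$point - P) < 1e-6) break
        P <- st$point
        dir <- st$direction
        R <- st$radius
        pts[[length(pts) + 1L]] <- P
        rad <- c(rad, R)
    }
    if (!converged)
        warning("tracking failed to reach the endpoint; returning partial curve")
    pruned <- pruneExcursions(do.call(rbind, pts), rad)
    Centerline(pruned$points, radius = pruned$radius, converged = converged)
}

# Remove out-and-back excursions: if a later point j >= i + 3 returns within
# 0.3 * local radius of point i, the detour between them is cut. A centerline
# between two cross-sections must not self-approach; detours can arise where
# a large adjacent structure (e.g. an aneurysm sac) briefly captures the
# crawler before it recovers.
pruneExcursions <- function(points, radius) {
    m <- nrow(points)
    keep <- logical(m)
    i <- 1L
    while (i <= m) {
        keep[i] <- TRUE
        j <- m
        cut <- i
        while (j >= i + 3L) {
            thr <- 0.3 * max(radius[i], radius[j], 1e-6)
            if (sqrt(sum((points[j, ] - points[i, ])^2)) < thr) {
                cut <- j
                break
            }
            j <- j - 1L
        }
        i <- if (cut > i) cut else i + 1L
    }
    list(points = points[keep, , drop = FALSE], radius = radius[keep])
}

#' Reverse the point order of a centerline
#'
#' @param centerline a \linkS4class{Centerline}.
#' @return The centerline traversed in the opposite direction (arc length
#'   recomputed from the new start).
#' @export
reverseCenterline <- function(centerline) {
    m <- nrow(centerline@points)
    Centerline(centerline@points[m:1, , drop = FALSE],
               radius = centerline@radius[m:1],
               curveType = centerline@curveType,
               level = centerline@level,
               branchIndex = centerline@branchIndex,
               converged = centerline@converged)
}

#' Cumulative arc length of an ordered point sequence
#'
#' @param points m x 3 matrix.
#' @return Numeric(m): 0 at the first point, then running sums of chord
#'   lengths.
#' @export
arcLength <- function(points) {
    points <- as.matrix(points)
    m <- nrow(points)
    if (m == 0L) return(numeric(0))
    if (m == 1L) return(0)
    seglen <- sqrt(rowSums((points[-1, , drop = FALSE] -
                            points[-m, , drop = FALSE])^2))
    c(0, cumsum(seglen))
}

#' Assign tree topology labels to a set of centerlines
#'
#' Levels are 0-based and rise distally (root = 0); branches on a level are
#' numbered from 1 by declining cross-section area. Ties are broken by the
#' order of appearance in \code{curves} (documented, deterministic).
#'
#' @param curves list of \linkS4class{Centerline}.
#' @param parent integer vector: index of each curve's parent in
#'   \code{curves}, NA for roots.
#' @param area numeric vector of representative cross-section areas, mm^2.
#' @return The list of curves with \code{level} and \code{branchIndex} set.
#' @export
assignTopology <- function(curves, parent, area) {
    n <- length(curves)
    stopifnot(length(parent) == n, length(area) == n)
    level <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
        lv <- 0L
        j <- i
        seen <- integer(0)
        while (!is.na(parent[j])) {
            if (j %in% seen) stop("cycle in parent links")
            seen <- c(seen, j)
            j <- parent[j]
            lv <- lv + 1L
            if (lv > n) stop("cycle in parent links")
        }
        level[i] <- lv
    }
    branch <- rep(NA_integer_, n)
    for (lv in sort(unique(level))) {
        sel <- which(level == lv)
        ord <- sel[order(-area[sel], sel)]
        branch[ord] <- seq_along(ord)
    }
    for (i in seq_len(n)) {
        curves[[i]]@level <- level[i]
        curves[[i]]@branchIndex <- branch[i]
    }
    curves
}

#' Serialize centerlines as CSV
#'
#' Columns: x, y, z, radius, arc length and curve type.
#'
#' @param centerline a \linkS4class{Centerline}.
#' @param path output path.
#' @export
writeCenterline <- function(centerline, path) {
    df <- data.frame(x = centerline@points[, 1], y = centerline@points[, 2],
                     z = centerline@points[, 3], radius = centerline@radius,
                     L = centerline@cumLength,
                     type = centerline@curveType)
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}
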