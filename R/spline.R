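# Degree-6 Bezier-spline approximation of centerlines with C3 joints, and
# curvature / torsion profiles derived from it. C3 continuity keeps the
# torsion function continuous across joints; degree 6 is the minimal degree
# that supports C3 joints with remaining fitting freedom per segment.

bernstein6 <- function(t) {
    cbind((1 - t)^6, 6 * t * (1 - t)^5, 15 * t^2 * (1 - t)^4,
          20 * t^3 * (1 - t)^3, 15 * t^4 * (1 - t)^2, 6 * t^5 * (1 - t),
          t^6)
}

# Resample a centerline at arc spacing = factor * local radius.
resampleByRadius <- function(centerline, factor) {
    pts <- centerline@points
    cum <- centerline@cumLength
    rad <- centerline@radius
    if (all(is.na(rad))) rad <- rep(mean(diff(cum)), length(cum))
    rad[is.na(rad) | rad <= 0] <- mean(rad[!is.na(rad) & rad > 0])
    total <- cum[length(cum)]
    s <- 0
    ss <- c()
    while (s < total) {
        ss <- c(ss, s)
        at <- polylineAt(pts, cum, s, rad)
        s <- s + max(factor * at$r, 1e-3)
    }
    ss <- c(ss, total)
    t(vapply(ss, function(si) polylineAt(pts, cum, si), numeric(3)))
}

#' Fit a C3 degree-6 Bezier spline to a centerline
#'
#' The centerline is resampled at an arc spacing proportional to the local
#' vessel radius (wider vessels need fewer control points), grouped into
#' degree-6 segments, and fitted per coordinate by equality-constrained
#' least squares: the spline interpolates the first and last point, and at
#' every joint position and the first three derivatives are tied between
#' neighboring segments (C3). Least squares gives the smoothing behavior:
#' the fitted curve is smoother than noisy input points.
#'
#' @param centerline a \linkS4class{Centerline} (or m x 3 matrix).
#' @param spacingFactor resampling arc spacing in multiples of the local
#'   radius.
#' @param maxPointsPerSegment joints are inserted at least every this many
#'   resampled points to bound segment length (degree-6 locality).
#' @param breakArcs optional arc positions (mm) where joints must lie, e.g.
#'   division split points when fitting across a bifurcation.
#' @param continuity 3 (default) or 2: continuity class enforced at joints
#'   (2 exposed for comparing torsion continuity).
#' @return A \linkS4class{BezierSpline}.
#' @export
fitSpline <- function(centerline, spacingFactor = 1.0,
                      maxPointsPerSegment = 20L, breakArcs = NULL,
                      continuity = 3L) {
    if (is.matrix(centerline))
        centerline <- Centerline(centerline)
    if (nrow(centerline@points) < 8L)
        stop("need at least 8 centerline points")
    P <- resampleByRadius(centerline, spacingFactor)
    if (nrow(P) < 8L) P <- centerline@points
    m <- nrow(P)
    u <- arcLength(P)   # chord-length parameterization

    bidx <- c(1L, m)
    if (!is.null(breakArcs)) {
        tot <- centerline@cumLength[length(centerline@cumLength)]
        frac <- pmin(1, pmax(0, breakArcs / tot))
        bidx <- c(bidx, vapply(frac * u[m], function(uu)
            which.min(abs(u - uu)), integer(1)))
    }
    bidx <- sort(unique(c(bidx, seq(1L, m, by = maxPointsPerSegment))))
    # drop boundaries that leave a segment too thin to fit
    keep <- c(TRUE, diff(bidx) >= 7L)
    keep[length(keep)] <- TRUE
    bidx <- bidx[keep]
    if (bidx[length(bidx)] != m) bidx[length(bidx)] <- m
    bidx <- unique(bidx)
    if (length(bidx) < 2L) bidx <- c(1L, m)
    if (m - bidx[length(bidx) - 1L] < 4L && length(bidx) > 2L)
        bidx <- bidx[-(length(bidx) - 1L)]
    K <- length(bidx) - 1L
    ub <- u[bidx]
    h <- diff(ub)

    ncoef <- 7L * K
    seg_of <- pmin(pmax(findInterval(u, ub, rightmost.closed = TRUE), 1L), K)
    A <- matrix(0, m, ncoef)
    for (i in seq_len(m)) {
        k <- seg_of[i]
        t <- (u[i] - ub[k]) / h[k]
        A[i, (k - 1L) * 7L + 1:7] <- bernstein6(t)
    }

    # equality constraints
    crows <- list(); cb <- list()
    unitrow <- function(k, j, w) {       # w * P_j of segment k (j 0-based)
        r <- numeric(ncoef)
        r[(k - 1L) * 7L + j + 1L] <- w
        r
    }
    crows[[1]] <- unitrow(1L, 0L, 1); cb[[1]] <- P[1, ]
    crows[[2]] <- unitrow(K, 6L, 1); cb[[2]] <- P[m, ]
    if (K > 1L) {
        d1 <- c(-1, 1); d2 <- c(1, -2, 1); d3 <- c(-1, 3, -3, 1)
        for (k in seq_len(K - 1L)) {
            r0 <- unitrow(k, 6L, 1) - unitrow(k + 1L, 0L, 1)
            crows[[length(crows) + 1L]] <- r0; cb[[length(cb) + 1L]] <- c(0, 0, 0)
            r1 <- (unitrow(k, 5L, d1[1]) + unitrow(k, 6L, d1[2])) / h[k] -
                  (unitrow(k + 1L, 0L, d1[1]) + unitrow(k + 1L, 1L, d1[2])) / h[k + 1L]
            crows[[length(crows) + 1L]] <- r1; cb[[length(cb) + 1L]] <- c(0, 0, 0)
            r2 <- (unitrow(k, 4L, d2[1]) + unitrow(k, 5L, d2[2]) +
                   unitrow(k, 6L, d2[3])) / h[k]^2 -
                  (unitrow(k + 1L, 0L, d2[3]) + unitrow(k + 1L, 1L, d2[2]) +
                   unitrow(k + 1L, 2L, d2[1])) / h[k + 1L]^2
            crows[[length(crows) + 1L]] <- r2; cb[[length(cb) + 1L]] <- c(0, 0, 0)
            if (continuity >= 3L) {
                r3 <- (unitrow(k, 3L, d3[1]) + unitrow(k, 4L, d3[2]) +
                       unitrow(k, 5L, d3[3]) + unitrow(k, 6L, d3[4])) / h[k]^3 -
                      (unitrow(k + 1L, 0L, -d3[4]) + unitrow(k + 1L, 1L, -d3[3]) +
                       unitrow(k + 1L, 2L, -d3[2]) + unitrow(k + 1L, 3L, -d3[1])) / h[k + 1L]^3
                crows[[length(crows) + 1L]] <- r3
                cb[[length(cb) + 1L]] <- c(0, 0, 0)
            }
        }
    }
    Cm <- do.call(rbind, crows)
    Db <- do.call(rbind, cb)
    nc <- nrow(Cm)

    AtA <- crossprod(A) + diag(1e-10, ncoef)
    KKT <- rbind(cbind(2 * AtA, t(Cm)), cbind(Cm, matrix(0, nc, nc)))
    rhs <- rbind(2 * crossprod(A, P), Db)
    sol <- solve(KKT, rhs)
    X <- sol[seq_len(ncoef), , drop = FALSE]

    segments <- lapply(seq_len(K), function(k)
        X[(k - 1L) * 7L + 1:7, , drop = FALSE])
    res <- A %*% X - P
    rms <- sqrt(mean(rowSums(res^2)))

    # arc map: dense cumulative integration of |dr/du| per segment
    uu <- c(); spd <- c()
    for (k in seq_len(K)) {
        tg <- seq(0, 1, length.out = 200L)
        D1 <- 6 * diff(segments[[k]]) / h[k]
        d1 <- bernstein5(tg) %*% D1
        uu <- c(uu, ub[k] + tg * h[k])
        spd <- c(spd, sqrt(rowSums(d1^2)))
    }
    dup <- c(FALSE, diff(uu) <= 0)
    uu <- uu[!dup]; spd <- spd[!dup]
    s <- c(0, cumsum((diff(uu)) * (head(spd, -1) + tail(spd, -1)) / 2))

    new("BezierSpline", segments = segments, breaks = ub,
        arcTable = cbind(u = uu, s = s), totalLength = s[length(s)],
        residualRMS = rms)
}

bernstein5 <- function(t) {
    cbind((1 - t)^5, 5 * t * (1 - t)^4, 10 * t^2 * (1 - t)^3,
          10 * t^3 * (1 - t)^2, 5 * t^4 * (1 - t), t^5)
}
bernstein4 <- function(t) {
    cbind((1 - t)^4, 4 * t * (1 - t)^3, 6 * t^2 * (1 - t)^2,
          4 * t^3 * (1 - t), t^4)
}
bernstein3 <- function(t) {
    cbind((1 - t)^3, 3 * t * (1 - t)^2, 3 * t^2 * (1 - t), t^3)
}

# u (global chord parameter) and derivatives of the spline w.r.t. u at
# arc positions s. Returns list(r, r1, r2, r3, u).
splineDerivsU <- function(spline, s) {
    tab <- spline@arcTable
    eps <- 1e-9 * max(1, spline@totalLength)
    if (any(s < -eps | s > spline@totalLength + eps))
        stop("arc position outside the spline domain")
    s <- pmin(pmax(s, 0), spline@totalLength)
    u <- approx(tab[, 2], tab[, 1], xout = s, ties = "ordered")$y
    ub <- spline@breaks
    K <- length(spline@segments)
    k <- pmin(pmax(findInterval(u, ub, rightmost.closed = TRUE), 1L), K)
    n <- length(s)
    r <- r1 <- r2 <- r3 <- matrix(NA_real_, n, 3L)
    for (i in seq_len(n)) {
        Q <- spline@segments[[k[i]]]
        hk <- ub[k[i] + 1L] - ub[k[i]]
        t <- (u[i] - ub[k[i]]) / hk
        D1 <- 6 * diff(Q)
        D2 <- 5 * diff(D1)
        D3 <- 4 * diff(D2)
        r[i, ] <- bernstein6(t) %*% Q
        r1[i, ] <- (bernstein5(t) %*% D1) / hk
        r2[i, ] <- (bernstein4(t) %*% D2) / hk^2
        r3[i, ] <- (bernstein3(t) %*% D3) / hk^3
    }
    list(r = r, r1 = r1, r2 = r2, r3 = r3, u = u)
}

#' Evaluate a Bezier spline at arc positions
#'
#' Positions (order 0) or derivatives with respect to arc length (orders
#' 1-3, chain-ruled through the chord-length parameterization; the order-1
#' result is the unit tangent).
#'
#' @param spline a \linkS4class{BezierSpline}.
#' @param s arc positions, mm (vectorized).
#' @param order 0 to 3.
#' @return length(s) x 3 matrix.
#' @export
evaluateSpline <- function(spline, s, order = 0L) {
    stopifnot(order %in% 0:3)
    d <- splineDerivsU(spline, s)
    if (order == 0L) return(d$r)
    v <- sqrt(rowSums(d$r1^2))
    if (any(v <= 0)) stop("degenerate parameterization: zero first derivative")
    us <- 1 / v
    if (order == 1L) return(d$r1 * us)
    vu <- rowSums(d$r1 * d$r2) / v
    uss <- -vu / v^3
    if (order == 2L) return(d$r2 * us^2 + d$r1 * uss)
    vuu <- (rowSums(d$r2^2) + rowSums(d$r1 * d$r3)) / v -
           (rowSums(d$r1 * d$r2))^2 / v^3
    usss <- (3 * vu^2 - v * vuu) / v^5
    d$r3 * us^3 + 3 * d$r2 * us * uss + d$r1 * usss
}

#' Curvature and torsion along a spline
#'
#' Computed analytically from the spline derivatives (the formulas are
#' parameterization invariant):
#' \deqn{\kappa = |r' x r''| / |r'|^3, \quad
#'       \tau = ((r' x r'') . r''') / |r' x r''|^2.}
#' Where curvature falls below \code{kappaFloor} the Frenet frame is
#' undefined and torsion is reported as 0 (straight stretches).
#'
#' @param spline a \linkS4class{BezierSpline}.
#' @param s arc positions, mm (vectorized).
#' @param kappaFloor curvature floor below which torsion is zeroed, rad/mm.
#' @return data.frame(s, kappa, tau), rad/mm.
#' @export
curvatureTorsion <- function(spline, s, kappaFloor = 1e-6) {
    d <- splineDerivsU(spline, s)
    n <- length(s)
    kappa <- tau <- numeric(n)
    for (i in seq_len(n)) {
        c12 <- cross3(d$r1[i, ], d$r2[i, ])
        v <- vnorm(d$r1[i, ])
        if (v <= 0) stop("degenerate parameterization: zero first derivative")
        kappa[i] <- vnorm(c12) / v^3
        tau[i] <- if (kappa[i] < kappaFloor) 0
                  else sum(c12 * d$r3[i, ]) / sum(c12^2)
    }
    data.frame(s = s, kappa = kappa, tau = tau)
}

#' Curvature/torsion statistics over an arc
#'
#' Samples curvature and torsion at a fixed arc step over the given range
#' (default: the whole spline) and reports the maximal curvature, mean
#' curvature and mean absolute torsion.
#'
#' @param spline a \linkS4class{BezierSpline}.
#' @param arcRange numeric(2) arc interval, mm.
#' @param step sampling step, mm.
#' @return An \linkS4class{ArcStats}.
#' @export
arcStats <- function(spline, arcRange = NULL, step = 0.05) {
    if (is.null(arcRange)) arcRange <- c(0, spline@totalLength)
    if (diff(arcRange) <= 0) stop("empty arc range")
    s <- unique(c(seq(arcRange[1], arcRange[2], by = step), arcRange[2]))
    ct <- curvatureTorsion(spline, s)
    new("ArcStats", Kmax = max(ct$kappa), Kav = mean(ct$kappa),
        Tav = mean(abs(ct$tau)), arcRange = as.numeric(arcRange))
}

#' Serialize a spline as JSON
#'
#' Control points per segment plus the joint parameter values.
#'
#' @param spline a \linkS4class{BezierSpline}.
#' @param path output .json path.
#' @export
writeSpline <- function(spline, path) {
    out <- list(degree = 6L, breaks = spline@breaks,
                totalLength = spline@totalLength,
                segments = lapply(spline@segments, function(s)
                    as.data.frame(s, col.names = c("x", "y", "z"))))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
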