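# Small geometric helpers shared across modules.

unitv <- function(v) {
    n <- sqrt(sum(v^2))
    if (n == 0) stop("cannot normalize a zero vector")
    v / n
}

vnorm <- function(v) sqrt(sum(v^2))

cross3 <- function(a, b) {
    c(a[2] * b[3] - a[3] * b[2],
      a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
}

#' Angle between two vectors
#'
#' @param u,v non-zero 3-D vectors.
#' @return Angle in degrees, in [0, 180].
#' @export
angleBetween <- function(u, v) {
    if (vnorm(u) == 0 || vnorm(v) == 0) stop("zero-length vector")
    # atan2 form is numerically stable near 0 and 180 degrees
    atan2(vnorm(cross3(u, v)), sum(u * v)) * 180 / pi
}

# Deterministic orthonormal in-plane basis (e1, e2) for a unit normal n.
planeBasis <- function(n) {
    n <- unitv(n)
    a <- if (abs(n[1]) <= abs(n[2]) && abs(n[1]) <= abs(n[3])) c(1, 0, 0)
         else if (abs(n[2]) <= abs(n[3])) c(0, 1, 0) else c(0, 0, 1)
    e1 <- unitv(cross3(n, a))
    e2 <- cross3(n, e1)
    list(e1 = e1, e2 = e2)
}

# Rotate unit vector `from` toward unit vector `to` by at most maxAngle rad.
rotateToward <- function(from, to, maxAngle) {
    ang <- atan2(vnorm(cross3(from, to)), sum(from * to))
    if (ang <= maxAngle) return(to)
    axis <- cross3(from, to)
    if (vnorm(axis) < 1e-12) return(from)  # antiparallel: no defined plane
    axis <- unitv(axis)
    rotateAbout(from, axis, maxAngle)
}

# Rodrigues rotation of v about unit axis by angle (radians).
rotateAbout <- function(v, axis, angle) {
    v * cos(angle) + cross3(axis, v) * sin(angle) +
        axis * sum(axis * v) * (1 - cos(angle))
}

# Evaluate with a temporarily fixed RNG seed, restoring the caller's stream.
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

# Minimal distance from point p to the polyline given by rows of pts.
pointPolylineDistance <- function(p, pts) {
    m <- nrow(pts)
    if (m == 1L) return(vnorm(p - pts[1, ]))
    a <- pts[-m, , drop = FALSE]
    b <- pts[-1, , drop = FALSE]
    ab <- b - a
    ap <- matrix(p, m - 1L, 3L, byrow = TRUE) - a
    den <- rowSums(ab^2)
    t <- pmin(1, pmax(0, ifelse(den > 0, rowSums(ap * ab) / den, 0)))
    q <- a + ab * t
    sqrt(min(rowSums((matrix(p, m - 1L, 3L, byrow = TRUE) - q)^2)))
}

# Resample a polyline at a fixed arc step; returns sample points and their
# arc positions (original vertices are not necessarily retained).
densePolyline <- function(pts, cum, step) {
    total <- cum[length(cum)]
    arc <- unique(c(seq(0, total, by = max(step, 1e-6)), total))
    list(points = t(vapply(arc, function(s) polylineAt(pts, cum, s),
                           numeric(3))),
         arc = arc)
}

# Linear interpolation of a position (and optional radius) along a polyline
# at arc position s (chordal cumulative length).
polylineAt <- function(pts, cum, s, radius = NULL) {
    if (nrow(pts) == 1L) {
        if (!is.null(radius)) return(list(p = pts[1, ], r = radius[1]))
        return(pts[1, ])
    }
    s <- max(cum[1], min(cum[length(cum)], s))
    i <- findInterval(s, cum, rightmost.closed = TRUE)
    i <- max(1L, min(i, nrow(pts) - 1L))
    den <- cum[i + 1L] - cum[i]
    t <- if (den > 0) (s - cum[i]) / den else 0
    out <- pts[i, ] * (1 - t) + pts[i + 1L, ] * t
    if (!is.null(radius)) {
        r <- radius[i] * (1 - t) + radius[i + 1L] * t
        return(list(p = out, r = r))
    }
    out
}
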