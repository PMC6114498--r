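# Generics and accessors for the core classes.

#' @rdname VoxelGrid-accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname VoxelGrid-accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname VoxelGrid-accessors
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))
#' @rdname VoxelGrid-accessors
#' @export
setGeneric("physExtent", function(x) standardGeneric("physExtent"))

#' Accessors for voxel-grid objects
#'
#' @param x a \linkS4class{VascVolume}, \linkS4class{SegmentationMask} or
#'   \linkS4class{DistanceMap}.
#' @return \code{voxelData}: the 3-D array; \code{voxelSpacing},
#'   \code{voxelOrigin}: numeric(3); \code{physExtent}: 2 x 3 matrix of the
#'   physical corner positions (voxel centers) in mm.
#' @name VoxelGrid-accessors
#' @aliases voxelData voxelSpacing voxelOrigin physExtent
NULL

setMethod("voxelData", "VoxelGrid", function(x) x@data)
setMethod("voxelSpacing", "VoxelGrid", function(x) x@spacing)
setMethod("voxelOrigin", "VoxelGrid", function(x) x@origin)
setMethod("physExtent", "VoxelGrid", function(x) {
    hi <- x@origin + (dim(x@data) - 1L) * x@spacing
    rbind(lo = x@origin, hi = hi)
})

setMethod("show", "VascVolume", function(object) {
    d <- dim(object@data)
    cat(sprintf("VascVolume: %d x %d x %d voxels, spacing %s mm\n",
                d[1], d[2], d[3],
                paste(format(object@spacing, digits = 3), collapse = " x ")))
    cat(sprintf("  HU range [%.1f, %.1f], origin (%s) mm\n",
                min(object@data), max(object@data),
                paste(format(object@origin, digits = 4), collapse = ", ")))
})

setMethod("show", "SegmentationMask", function(object) {
    d <- dim(object@data)
    cat(sprintf("SegmentationMask: %d x %d x %d voxels, %d inside (threshold >= %g HU)\n",
                d[1], d[2], d[3], sum(object@data), object@thresholdLow))
})

setMethod("show", "DistanceMap", function(object) {
    d <- dim(object@data)
    cat(sprintf("DistanceMap: %d x %d x %d voxels, max distance %.3f mm\n",
                d[1], d[2], d[3], max(object@data)))
})

#' @rdname Centerline-accessors
#' @export
setGeneric("clPoints", function(x) standardGeneric("clPoints"))
#' @rdname Centerline-accessors
#' @export
setGeneric("clRadius", function(x) standardGeneric("clRadius"))
#' @rdname Centerline-accessors
#' @export
setGeneric("clCumLength", function(x) standardGeneric("clCumLength"))
#' @rdname Centerline-accessors
#' @export
setGeneric("curveType", function(x) standardGeneric("curveType"))
#' @rdname Centerline-accessors
#' @export
setGeneric("curveType<-", function(x, value) standardGeneric("curveType<-"))
#' @rdname Centerline-accessors
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' Accessors for Centerline objects
#'
#' @param x a \linkS4class{Centerline}.
#' @param value integer curve-type label.
#' @return \code{clPoints}: m x 3 matrix; \code{clRadius}, \code{clCumLength}:
#'   numeric(m); \code{curveType}: integer; \code{topology}: named integer
#'   vector (level, branchIndex).
#' @name Centerline-accessors
#' @aliases clPoints clRadius clCumLength curveType curveType<- topology
NULL

setMethod("clPoints", "Centerline", function(x) x@points)
setMethod("clRadius", "Centerline", function(x) x@radius)
setMethod("clCumLength", "Centerline", function(x) x@cumLength)
setMethod("curveType", "Centerline", function(x) x@curveType)
setMethod("curveType<-", "Centerline", function(x, value) {
    x@curveType <- as.integer(value)
    x
})
setMethod("topology", "Centerline", function(x)
    c(level = x@level, branchIndex = x@branchIndex))

setMethod("show", "Centerline", function(object) {
    m <- nrow(object@points)
    cat(sprintf("Centerline: %d points, length %.2f mm", m,
                if (m) object@cumLength[m] else 0))
    if (!is.na(object@curveType)) cat(sprintf(", type %d", object@curveType))
    if (!is.na(object@level))
        cat(sprintf(", level %d branch %d", object@level, object@branchIndex))
    if (!object@converged) cat(" [did not reach endpoint]")
    cat("\n")
})

setMethod("show", "PhantomSpec", function(object) {
    cat(sprintf("PhantomSpec(%s): D = %g, R1 = %g%s mm; C = %g HU, a = %g\n",
                object@kind, object@D, object@R1,
                if (object@kind == "helix") sprintf(", R2 = %g", object@R2) else "",
                object@Cb, object@a))
})

setMethod("show", "ABZParams", function(object) {
    cat(sprintf(
        "ABZParams: A1 = %.1f, A2 = %.1f deg (tilts %.1f, %.1f); DT = %.2f, D1 = %.2f, D2 = %.2f, Dan = %.2f mm\n",
        object@A1, object@A2, object@A1pl, object@A2pl,
        object@DT, object@D1, object@D2, object@Dan))
})

setMethod("show", "GroundTruth", function(object) {
    cat(sprintf("GroundTruth(%s): arc range [%.2f, %.2f] mm\n",
                object@kind, object@arcRange[1], object@arcRange[2]))
    if (!is.null(object@geometry$trueBA))
        cat(sprintf("  true BA %.2f deg, VA (%.2f, %.2f) deg\n",
                    object@geometry$trueBA, object@geometry$trueVA[1],
                    object@geometry$trueVA[2]))
})

setMethod("show", "CrossSection", function(object) {
    cat(sprintf(
        "CrossSection: d_min %.3f, d_max %.3f, d_avg %.3f mm; area %.3f mm^2 (%d border points)\n",
        object@dMin, object@dMax, object@dAvg, object@area,
        nrow(object@border)))
})

setMethod("show", "BifurcationZone", function(object) {
    cat(sprintf("BifurcationZone: BA %.2f deg, VA (%.2f, %.2f) deg, dominant branch %d\n",
                object@BA, object@VA1, object@VA2, object@dominant))
    cat(sprintf("  CoI trunk %.3f, branches (%.3f, %.3f); split point (%s) mm\n",
                object@CoIT, object@CoI1, object@CoI2,
                paste(sprintf("%.2f", object@T0), collapse = ", ")))
})

setMethod("show", "BezierSpline", function(object) {
    cat(sprintf("BezierSpline: %d degree-6 segment(s), C3 joints, length %.2f mm, fit RMS %.4g mm\n",
                length(object@segments), object@totalLength,
                object@residualRMS))
})

setMethod("show", "ArcStats", function(object) {
    cat(sprintf("ArcStats over [%.2f, %.2f] mm: Kmax %.4g, Kav %.4g, Tav %.4g rad/mm\n",
                object@arcRange[1], object@arcRange[2], object@Kmax,
                object@Kav, object@Tav))
})
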