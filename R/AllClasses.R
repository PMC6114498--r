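#' @useDynLib vasctree, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats optim optimize sd median approx runif cov
#' @importFrom utils head tail
NULL

# ---------------------------------------------------------------------------
# Voxel grids
# ---------------------------------------------------------------------------

#' Virtual parent of all voxel-grid classes
#'
#' A 3-D scalar grid with physical voxel spacing and origin. The physical
#' position of voxel (i, j, k) (0-based) is \code{origin + c(i, j, k) * spacing};
#' all geometry in the package is done in physical millimetre coordinates.
#'
#' @slot data 3-D array of voxel values.
#' @slot spacing numeric(3), per-axis voxel size in mm.
#' @slot origin numeric(3), physical position of voxel (0, 0, 0) in mm.
#' @keywords internal
setClass("VoxelGrid",
    representation("VIRTUAL",
        data = "array", spacing = "numeric", origin = "numeric"))

validVoxelGrid <- function(object) {
    msg <- NULL
    d <- dim(object@data)
    if (length(d) != 3L) msg <- c(msg, "data must be a 3-D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        msg <- c(msg, "spacing must be 3 positive finite values")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
        msg <- c(msg, "origin must be 3 finite values")
    if (length(d) == 3L && any(d < 2L))
        msg <- c(msg, "grid dimensions must be >= 2 per axis")
    if (is.null(msg)) TRUE else msg
}

#' 3-D scalar volume in Hounsfield Units
#'
#' @slot data 3-D numeric array of HU values, all finite.
#' @slot spacing,origin see \linkS4class{VoxelGrid}.
#' @seealso [VascVolume()] for the constructor.
#' @export
setClass("VascVolume", contains = "VoxelGrid")

setValidity("VascVolume", function(object) {
    msg <- validVoxelGrid(object)
    if (!isTRUE(msg)) return(msg)
    if (any(!is.finite(object@data))) return("all voxel values must be finite")
    TRUE
})

#' Binary segmentation mask aligned to a volume
#'
#' @slot data 3-D logical array.
#' @slot thresholdLow lower HU threshold the mask was produced with.
#' @export
setClass("SegmentationMask", contains = "VoxelGrid",
    representation(thresholdLow = "numeric"))

setValidity("SegmentationMask", function(object) {
    msg <- validVoxelGrid(object)
    if (!isTRUE(msg)) return(msg)
    if (!is.logical(object@data)) return("mask data must be logical")
    TRUE
})

#' Euclidean distance map (mm) of a segmentation mask
#'
#' Each inside voxel holds the minimal Euclidean distance (in mm, honoring
#' anisotropic spacing) to the nearest background voxel center; background
#' voxels hold zero.
#'
#' @export
setClass("DistanceMap", contains = "VoxelGrid")

setValidity("DistanceMap", function(object) {
    msg <- validVoxelGrid(object)
    if (!isTRUE(msg)) return(msg)
    if (any(object@data < 0)) return("distances must be non-negative")
    TRUE
})

#' Construct a VascVolume
#'
#' @param data 3-D numeric array (HU).
#' @param spacing numeric(3) voxel size, mm.
#' @param origin numeric(3) physical position of voxel (0,0,0), mm.
#' @return A \linkS4class{VascVolume}.
#' @examples
#' v <- VascVolume(array(0, c(4, 4, 4)), spacing = c(1, 1, 1))
#' @export
VascVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    new("VascVolume", data = data, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

# ---------------------------------------------------------------------------
# Phantom specifications
# ---------------------------------------------------------------------------

#' Parameters of a synthetic torus or helix vessel phantom
#'
#' @slot kind "torus" or "helix".
#' @slot D vessel diameter, mm.
#' @slot R1 basal radius of the sweep, mm.
#' @slot R2 axial rise per turn (helix only), mm.
#' @slot Cb HU value at the vessel boundary (the profile's C parameter).
#' @slot a slope coefficient of the sigmoid HU falloff.
#' @export
setClass("PhantomSpec",
    representation(kind = "character", D = "numeric", R1 = "numeric",
                   R2 = "numeric", Cb = "numeric", a = "numeric"))

setValidity("PhantomSpec", function(object) {
    msg <- NULL
    if (!object@kind %in% c("torus", "helix"))
        msg <- c(msg, "kind must be 'torus' or 'helix'")
    if (object@D <= 0) msg <- c(msg, "D must be positive")
    if (object@R1 < 2 * object@D)
        msg <- c(msg, "R1 must be >= 2 * D (self-overlap rejection rule)")
    if (object@kind == "helix" &&
        (is.na(object@R2) || object@R2 < 2 * object@D))
        msg <- c(msg, "helix R2 must be >= 2 * D (self-overlap rejection rule)")
    if (object@Cb <= 0) msg <- c(msg, "C must be positive")
    if (object@a <= 0) msg <- c(msg, "a must be positive")
    if (is.null(msg)) TRUE else msg
})

#' Construct a PhantomSpec
#'
#' @param kind "torus" or "helix".
#' @param D,R1,R2 geometry in mm (R2 only for helix: axial rise per turn).
#' @param C,a sigmoid HU profile parameters (boundary HU and slope).
#' @export
PhantomSpec <- function(kind, D, R1, R2 = NA_real_, C = 150, a = 10) {
    # slot is named Cb: a slot literally named C would partially match the
    # Class argument of new()
    new("PhantomSpec", kind = kind, D = D, R1 = R1, R2 = as.numeric(R2),
        Cb = C, a = a)
}

#' Parameters of an artificial bifurcation zone (ABZ) phantom
#'
#' A straight trunk splitting into two straight branches, optionally with a
#' spherical aneurysm at the apex. Angles in degrees, diameters in mm.
#'
#' @slot A1,A2 branch angles from the trunk axis.
#' @slot A1pl,A2pl out-of-division-plane tilts.
#' @slot wAn aneurysm weight parameter (stored; no geometric effect).
#' @slot DT,D1,D2 trunk and branch diameters.
#' @slot Dan aneurysm diameter.
#' @export
setClass("ABZParams",
    representation(A1 = "numeric", A2 = "numeric", A1pl = "numeric",
                   A2pl = "numeric", wAn = "numeric", DT = "numeric",
                   D1 = "numeric", D2 = "numeric", Dan = "numeric"))

#' Construct ABZ phantom parameters
#'
#' Values outside the anatomically motivated ranges (see [abzRanges()])
#' raise a warning, not an error: the ranges are anatomical, not mathematical,
#' limits.
#'
#' @param A1,A2 branch angles from trunk axis, degrees.
#' @param A1pl,A2pl out-of-plane tilts, degrees.
#' @param wAn aneurysm weight parameter (dimensionless, stored only).
#' @param DT,D1,D2,Dan trunk, branch and aneurysm diameters, mm.
#' @export
ABZParams <- function(A1, A2, A1pl = 0, A2pl = 0, wAn = 0,
                      DT = 4, D1 = 3.5, D2 = 2.5, Dan = 4) {
    rg <- abzRanges()
    vals <- c(A1 = A1, A2 = A2, A1pl = A1pl, A2pl = A2pl, wAn = wAn,
              DT = DT, D1 = D1, D2 = D2, Dan = Dan)
    for (nm in names(vals)) {
        r <- rg[[nm]]
        if (vals[[nm]] < r[1] || vals[[nm]] > r[2])
            warning(sprintf("ABZ parameter %s = %g outside anatomical range [%g, %g]",
                            nm, vals[[nm]], r[1], r[2]))
    }
    new("ABZParams", A1 = A1, A2 = A2, A1pl = A1pl, A2pl = A2pl, wAn = wAn,
        DT = DT, D1 = D1, D2 = D2, Dan = Dan)
}

#' Anatomical parameter ranges for ABZ phantoms
#'
#' @return Named list of c(min, max) per parameter.
#' @export
abzRanges <- function() {
    list(A1 = c(15, 80), A2 = c(15, 80), A1pl = c(-15, 15), A2pl = c(-15, 15),
         wAn = c(0, 0.15), DT = c(3.5, 4.5), D1 = c(2.5, 4.2),
         D2 = c(2.0, 3.0), Dan = c(2, 6))
}

#' Analytic ground truth attached to a phantom
#'
#' @slot kind phantom kind ("torus", "helix" or "abz").
#' @slot centerline function(s): arc-length parameterized 3-D curve, mm.
#' @slot arcRange numeric(2), arc-length domain of \code{centerline}, mm.
#' @slot radius function(s): local vessel radius, mm.
#' @slot distanceTo function(p): minimal distance from 3-D point(s) to the
#'   analytic centerline, mm.
#' @slot curvature,torsion analytic curvature/torsion, rad/mm (NA for ABZ).
#' @slot geometry list of construction details (direction vectors, true
#'   angles, true coplanarity indices, apex, seed points, ...).
#' @export
setClass("GroundTruth",
    representation(kind = "character", centerline = "function",
                   arcRange = "numeric", radius = "function",
                   distanceTo = "function", curvature = "numeric",
                   torsion = "numeric", geometry = "list"))

setValidity("GroundTruth", function(object) {
    msg <- NULL
    if (length(object@arcRange) != 2L || diff(object@arcRange) < 0)
        msg <- c(msg, "arcRange must be a non-decreasing length-2 numeric")
    p <- object@centerline(object@arcRange[1])
    if (any(!is.finite(p))) msg <- c(msg, "centerline not finite on its domain")
    g <- object@geometry
    if (!is.null(g$trueBA) && (g$trueBA <= 0 || g$trueBA >= 180))
        msg <- c(msg, "true BA must lie in (0, 180) degrees")
    if (!is.null(g$trueCoI) && (any(g$trueCoI < 0) || any(g$trueCoI > 1)))
        msg <- c(msg, "true CoI must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

# ---------------------------------------------------------------------------
# Centerlines, cross sections, zones, splines
# ---------------------------------------------------------------------------

#' An ordered vessel centerline
#'
#' @slot points m x 3 matrix of positions, mm.
#' @slot radius local maximal-inscribed-ball radius at each point, mm.
#' @slot cumLength cumulative chordal arc length per point (0 at the first
#'   point), mm.
#' @slot curveType integer label (1 = curve to an aneurysm sac; 2, 3, ... =
#'   successive branches; NA = unlabeled).
#' @slot level,branchIndex tree topology (0-based level, 1-based branch
#'   number on its level).
#' @slot converged did tracking reach its endpoint.
#' @export
setClass("Centerline",
    representation(points = "matrix", radius = "numeric",
                   cumLength = "numeric", curveType = "integer",
                   level = "integer", branchIndex = "integer",
                   converged = "logical"))

setValidity("Centerline", function(object) {
    msg <- NULL
    m <- nrow(object@points)
    if (ncol(object@points) != 3L) msg <- c(msg, "points must be m x 3")
    if (length(object@cumLength) != m)
        msg <- c(msg, "cumLength length must match points")
    else if (m > 0) {
        if (object@cumLength[1] != 0) msg <- c(msg, "cumLength must start at 0")
        if (m > 1 && any(diff(object@cumLength) <= 0))
            msg <- c(msg, "cumLength must be strictly increasing")
    }
    if (length(object@radius) != m)
        msg <- c(msg, "radius length must match points")
    if (is.null(msg)) TRUE else msg
})

#' Construct a Centerline from ordered points
#'
#' Cumulative arc length is the running sum of chord lengths between
#' consecutive points.
#'
#' @param points m x 3 matrix of positions, mm.
#' @param radius local radius per point, mm (NA allowed).
#' @param curveType,level,branchIndex optional labels.
#' @param converged logical, tracking termination status.
#' @export
Centerline <- function(points, radius = rep(NA_real_, nrow(points)),
                       curveType = NA_integer_, level = NA_integer_,
                       branchIndex = NA_integer_, converged = TRUE) {
    points <- as.matrix(points)
    storage.mode(points) <- "double"
    new("Centerline", points = points, radius = as.numeric(radius),
        cumLength = arcLength(points), curveType = as.integer(curveType),
        level = as.integer(level), branchIndex = as.integer(branchIndex),
        converged = converged)
}

#' A measured, oriented vessel cross-section
#'
#' @slot center geometric center P_sc, mm.
#' @slot normal unit plane normal (local vessel axis).
#' @slot border n x 3 matrix of ordered border points.
#' @slot dMin,dMax,dAvg diameters, mm; dAvg = sqrt(4 * area / pi).
#' @slot area triangle-fan cross-section area, mm^2.
#' @slot flags per-ray integer flags (0 ok, 1 hit sampling bounds).
#' @export
setClass("CrossSection",
    representation(center = "numeric", normal = "numeric", border = "matrix",
                   dMin = "numeric", dMax = "numeric", dAvg = "numeric",
                   area = "numeric", flags = "integer"))

setValidity("CrossSection", function(object) {
    msg <- NULL
    if (object@area <= 0) msg <- c(msg, "area must be positive")
    if (object@dMin > object@dMax) msg <- c(msg, "dMin must be <= dMax")
    if (is.null(msg)) TRUE else msg
})

#' A vessel division (bifurcation) zone
#'
#' Trunk points Tr are numbered from the split point against the flow;
#' branch points Br with the flow. The division plane passes through the
#' three 0-points; angles are computed from the vessel directional vectors
#' (trunk: Tr1 -> Tr0, branches: Br0 -> Br1).
#'
#' @slot T0 split point, mm.
#' @slot Tr,Br1,Br2 point matrices (row 1 = point 0).
#' @slot TrRadius,Br1Radius,Br2Radius local radii at those points, mm.
#' @slot DPoint,DPN division-plane point and unit normal.
#' @slot VDVT,VDV1,VDV2 unit direction vectors (trunk downstream, branches).
#' @slot BA,VA1,VA2 branching and vessel angles, degrees.
#' @slot CoIT,CoI1,CoI2 coplanarity indices in [0, 1].
#' @slot dominant 1 or 2: branch with the larger mean radius.
#' @export
setClass("BifurcationZone",
    representation(T0 = "numeric", Tr = "matrix", Br1 = "matrix",
                   Br2 = "matrix", TrRadius = "numeric", Br1Radius = "numeric",
                   Br2Radius = "numeric", DPoint = "numeric", DPN = "numeric",
                   VDVT = "numeric", VDV1 = "numeric", VDV2 = "numeric",
                   BA = "numeric", VA1 = "numeric", VA2 = "numeric",
                   CoIT = "numeric", CoI1 = "numeric", CoI2 = "numeric",
                   dominant = "integer"))

setValidity("BifurcationZone", function(object) {
    msg <- NULL
    if (any(c(object@CoIT, object@CoI1, object@CoI2) < 0) ||
        any(c(object@CoIT, object@CoI1, object@CoI2) > 1))
        msg <- c(msg, "CoI must lie in [0, 1]")
    for (nm in c("BA", "VA1", "VA2")) {
        v <- slot(object, nm)
        if (v < 0 || v > 180) msg <- c(msg, paste(nm, "must lie in [0, 180]"))
    }
    if (is.null(msg)) TRUE else msg
})

#' A degree-6 Bezier spline with C3 joints
#'
#' @slot segments list of 7 x 3 control-point matrices.
#' @slot breaks chord-length parameter values at segment boundaries
#'   (length = number of segments + 1).
#' @slot arcTable two-column matrix (u, s) mapping the global chord-length
#'   parameter to arc length, strictly increasing in both columns.
#' @slot totalLength total arc length, mm.
#' @slot residualRMS RMS distance of the fitted data points to the spline, mm.
#' @export
setClass("BezierSpline",
    representation(segments = "list", breaks = "numeric", arcTable = "matrix",
                   totalLength = "numeric", residualRMS = "numeric"))

setValidity("BezierSpline", function(object) {
    msg <- NULL
    if (!all(vapply(object@segments, function(s)
            is.matrix(s) && all(dim(s) == c(7L, 3L)), logical(1))))
        msg <- c(msg, "each segment must be a 7 x 3 control-point matrix")
    if (length(object@breaks) != length(object@segments) + 1L)
        msg <- c(msg, "breaks must have one more entry than segments")
    if (any(diff(object@arcTable[, 2]) < 0))
        msg <- c(msg, "arc map must be monotone")
    if (is.null(msg)) TRUE else msg
})

#' Curvature/torsion statistics over a centerline arc
#'
#' @slot Kmax,Kav maximal and mean curvature, rad/mm.
#' @slot Tav mean absolute torsion, rad/mm.
#' @slot arcRange the arc interval the statistics cover, mm.
#' @export
setClass("ArcStats",
    representation(Kmax = "numeric", Kav = "numeric", Tav = "numeric",
                   arcRange = "numeric"))

setValidity("ArcStats", function(object) {
    if (object@Kmax < object@Kav - 1e-12) return("Kmax must be >= Kav")
    if (object@Kav < 0 || object@Tav < 0) return("Kav and Tav must be >= 0")
    TRUE
})
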