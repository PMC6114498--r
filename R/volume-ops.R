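# Volume preprocessing: VOI extraction, tricubic resampling, HU threshold
# segmentation and the Euclidean distance map that drives centerline tracking.

#' Extract a volume of interest (VOI)
#'
#' Returns the sub-volume whose voxel centers cover the given axis-aligned
#' physical box, preserving spacing and adjusting the origin.
#'
#' @param volume a \linkS4class{VascVolume}.
#' @param box numeric(6) \code{c(x0, y0, z0, x1, y1, z1)} or a 2 x 3 matrix
#'   (rows = lower/upper corner), physical mm coordinates.
#' @return A \linkS4class{VascVolume} covering the box.
#' @export
extractVOI <- function(volume, box) {
    stopifnot(is(volume, "VascVolume"))
    if (is.matrix(box)) box <- c(box[1, ], box[2, ])
    lo <- pmin(box[1:3], box[4:6])
    hi <- pmax(box[1:3], box[4:6])
    ext <- physExtent(volume)
    if (any(hi < ext[1, ]) || any(lo > ext[2, ]))
        stop("VOI box does not intersect the volume extent")
    sp <- volume@spacing
    i0 <- pmax(0L, floor((lo - volume@origin) / sp))
    i1 <- pmin(dim(volume@data) - 1L, ceiling((hi - volume@origin) / sp))
    if (any(i1 < i0)) stop("VOI box does not intersect the volume extent")
    idx <- lapply(1:3, function(k) seq.int(i0[k] + 1L, i1[k] + 1L))
    VascVolume(volume@data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
               spacing = sp, origin = volume@origin + i0 * sp)
}

#' Resample a volume with tricubic interpolation
#'
#' Values are interpolated on the physical grid with a separable cubic
#' convolution kernel (Keys, a = -0.5), which reproduces constant and linear
#' fields exactly. The output grid keeps the input origin and covers the same
#' physical extent.
#'
#' @param volume a \linkS4class{VascVolume}.
#' @param targetSpacing numeric scalar or numeric(3), new voxel size in mm.
#' @return A resampled \linkS4class{VascVolume}.
#' @export
resampleTricubic <- function(volume, targetSpacing = 0.2) {
    stopifnot(is(volume, "VascVolume"))
    if (length(targetSpacing) == 1L) targetSpacing <- rep(targetSpacing, 3L)
    if (any(targetSpacing <= 0)) stop("targetSpacing must be positive")
    if (any(targetSpacing > volume@spacing))
        message("resampleTricubic: target spacing coarser than source (downsampling)")
    d <- dim(volume@data)
    extent <- (d - 1L) * volume@spacing
    odim <- as.integer(floor(extent / targetSpacing + 1e-9)) + 1L
    out <- cpp_resample_tricubic(volume@data, d, volume@spacing,
                                 volume@origin, odim, targetSpacing,
                                 volume@origin)
    VascVolume(array(out, odim), spacing = targetSpacing,
               origin = volume@origin)
}

#' Sample a voxel grid at arbitrary physical points
#'
#' Tricubic interpolation of a \linkS4class{VascVolume} or
#' \linkS4class{DistanceMap} at physical mm positions.
#'
#' @param grid a \linkS4class{VascVolume} or \linkS4class{DistanceMap}.
#' @param points numeric(3) or an m x 3 matrix of positions, mm.
#' @return Numeric vector of interpolated values.
#' @export
sampleGrid <- function(grid, points) {
    stopifnot(is(grid, "VoxelGrid"))
    if (!is.matrix(points)) points <- matrix(points, ncol = 3L, byrow = TRUE)
    storage.mode(points) <- "double"
    d <- grid@data
    if (!is.double(d)) storage.mode(d) <- "double"
    cpp_sample_tricubic(d, dim(d), grid@spacing, grid@origin, points)
}

#' Threshold segmentation of a HU volume
#'
#' Voxels with value >= \code{low} become foreground. Connected-component
#' selection is deliberately left to callers.
#'
#' @param volume a \linkS4class{VascVolume}.
#' @param low lower HU threshold; values in [100, 150] are the intended
#'   working range (lower values suit strictly arterial-phase studies), a
#'   warning is raised outside it.
#' @return A \linkS4class{SegmentationMask}.
#' @export
segmentThreshold <- function(volume, low = 150) {
    stopifnot(is(volume, "VascVolume"))
    if (low < 100 || low > 150)
        warning(sprintf("threshold %g HU outside the intended [100, 150] range", low))
    new("SegmentationMask", data = volume@data >= low,
        spacing = volume@spacing, origin = volume@origin, thresholdLow = low)
}

#' Euclidean distance map of a segmentation mask
#'
#' Exact Euclidean distance transform in physical units (anisotropic voxel
#' spacing honored): each foreground voxel receives the distance to the
#' nearest background voxel center; background voxels are zero. The maxima
#' of this map along a vessel approximate the local maximal inscribed-ball
#' radius and drive centerline tracking.
#'
#' @param mask a \linkS4class{SegmentationMask}.
#' @return A \linkS4class{DistanceMap}.
#' @export
distanceMap <- function(mask) {
    stopifnot(is(mask, "SegmentationMask"))
    if (!any(mask@data)) stop("empty mask: no foreground voxels")
    d <- cpp_edt(mask@data, dim(mask@data), mask@spacing)
    new("DistanceMap", data = array(d, dim(mask@data)),
        spacing = mask@spacing, origin = mask@origin)
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers around \pkg{RNifti} preserving spacing and origin through
#' the sform matrix; a write/read round trip reproduces them bit-exactly.
#'
#' @param volume a \linkS4class{VascVolume}.
#' @param path file path (.nii or .nii.gz).
#' @return \code{readVolume}: a \linkS4class{VascVolume};
#'   \code{writeVolume}: the path, invisibly.
#' @export
writeVolume <- function(volume, path) {
    stopifnot(is(volume, "VascVolume"))
    img <- RNifti::asNifti(volume@data)
    m <- diag(c(volume@spacing, 1))
    m[1:3, 4] <- volume@origin
    RNifti::sform(img) <- structure(m, code = 2L)
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
    img <- RNifti::readNifti(path)
    x <- RNifti::xform(img)
    sp <- sqrt(colSums(x[1:3, 1:3]^2))
    VascVolume(array(as.numeric(img), dim(img)), spacing = sp,
               origin = x[1:3, 4])
}
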