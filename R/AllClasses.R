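#' @import methods
NULL

#' Reference centerline with per-point radii
#'
#' Ordered samples of a vessel centerline in world (mm) coordinates, each
#' carrying the local lumen radius. This is both the ground-truth object the
#' accuracy metrics compare against and the seed of the union-of-spheres
#' phantom rasterizer.
#'
#' @slot points numeric matrix with columns `x`, `y`, `z`, `r` (all mm).
#' @slot label free-text identifier (dataset/vessel id).
#'
#' @seealso [readReference()], [simulateCenterline()], [voxelizeSpheres()]
#' @export
setClass("ReferenceCenterline",
         representation(points = "matrix", label = "character"))

setValidity("ReferenceCenterline", function(object) {
    p <- object@points
    if (!is.numeric(p) || ncol(p) != 4L)
        return("'points' must be a numeric matrix with 4 columns (x, y, z, r)")
    if (nrow(p) < 1L)
        return("a centerline needs at least 1 point")
    if (any(!is.finite(p)))
        return("'points' contains non-finite values")
    if (any(p[, 4L] <= 0))
        return("all radii must be > 0")
    if (nrow(p) >= 2L) {
        d <- diff(p[, 1:3, drop = FALSE])
        if (any(rowSums(abs(d)) == 0))
            return("consecutive centerline points must be distinct")
    }
    if (length(object@label) != 1L)
        return("'label' must be a single string")
    TRUE
})

#' Construct a ReferenceCenterline
#'
#' @param points numeric matrix (n x 4): x, y, z coordinates and radius,
#'   all in millimetres.
#' @param label identifier string.
#' @return A [ReferenceCenterline-class] object.
#' @export
ReferenceCenterline <- function(points, label = "") {
    points <- as.matrix(points)
    storage.mode(points) <- "double"
    colnames(points) <- c("x", "y", "z", "r")
    new("ReferenceCenterline", points = points, label = as.character(label))
}

#' Binary occupancy volume
#'
#' A 3D voxel grid of 0/1 values with isotropic voxel size and a world-space
#' origin. Voxel centers carry the world coordinates: the (0-based) voxel
#' index `(i, j, k)` sits at `origin + c(i, j, k) * voxelSize` mm. Array axes
#' map directly onto world axes (i, j, k) = (x, y, z); no permutation.
#'
#' @slot grid integer 3D array of 0/1.
#' @slot voxelSize scalar voxel edge length in mm.
#' @slot origin length-3 mm position of voxel index (0, 0, 0).
#'
#' @seealso [readVolume()], [voxelizeSpheres()], [voxelToMm()]
#' @export
setClass("BinaryVolume",
         representation(grid = "array", voxelSize = "numeric",
                        origin = "numeric"))

setValidity("BinaryVolume", function(object) {
    g <- object@grid
    if (length(dim(g)) != 3L)
        return("'grid' must be a 3D array")
    if (length(g) == 0L)
        return("'grid' must be non-empty")
    rg <- range(g)
    if (is.na(rg[1L]) || rg[1L] < 0 || rg[2L] > 1)
        return("'grid' values must be 0 or 1")
    if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
        object@voxelSize <= 0)
        return("'voxelSize' must be a positive scalar (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
        return("'origin' must be a finite length-3 vector (mm)")
    TRUE
})

#' Construct a BinaryVolume
#'
#' Values different from zero are binarized to 1.
#'
#' @param grid 3D array; coerced to integer 0/1.
#' @param voxelSize voxel edge length in mm (isotropic).
#' @param origin mm position of voxel index (0, 0, 0).
#' @return A [BinaryVolume-class] object.
#' @export
BinaryVolume <- function(grid, voxelSize = 0.1, origin = c(0, 0, 0)) {
    grid <- (grid != 0) + 0L
    storage.mode(grid) <- "integer"
    new("BinaryVolume", grid = grid, voxelSize = as.numeric(voxelSize),
        origin = as.numeric(origin))
}

#' Extracted centerline polyline
#'
#' An ordered 3D polyline in mm together with the cumulative arc length at
#' each point. This is the extractor's output and the form the accuracy
#' metrics evaluate after arc-length resampling.
#'
#' @slot points numeric matrix with columns `x`, `y`, `z` (mm).
#' @slot arcLengths cumulative polyline distance per point (mm), starting at 0.
#'
#' @seealso [orderPoints()], [resampleCenterline()], [evaluateCenterline()]
#' @export
setClass("Centerline",
         representation(points = "matrix", arcLengths = "numeric"))

setValidity("Centerline", function(object) {
    p <- object@points
    if (!is.numeric(p) || ncol(p) != 3L)
        return("'points' must be a numeric matrix with 3 columns (x, y, z)")
    if (nrow(p) < 2L)
        return("a centerline needs at least 2 points")
    if (any(!is.finite(p)))
        return("'points' contains non-finite values")
    al <- object@arcLengths
    if (length(al) != nrow(p))
        return("'arcLengths' must have one entry per point")
    if (al[1L] != 0 || any(diff(al) < 0))
        return("'arcLengths' must start at 0 and be non-decreasing")
    TRUE
})

#' Construct a Centerline
#'
#' Cumulative arc lengths are computed from the point sequence.
#'
#' @param points numeric matrix (n x 3) of mm coordinates, in path order.
#' @return A [Centerline-class] object.
#' @export
Centerline <- function(points) {
    points <- as.matrix(points)
    storage.mode(points) <- "double"
    colnames(points) <- c("x", "y", "z")
    seg <- sqrt(rowSums(diff(points)^2))
    new("Centerline", points = points, arcLengths = c(0, cumsum(seg)))
}

#' Per-axis medial surface
#'
#' The stack of per-slice 2D Voronoi skeletons obtained when slicing a
#' volume perpendicular to one coordinate axis, snapped to the voxel grid.
#'
#' @slot voxels integer matrix (n x 3) of 0-based voxel indices.
#' @slot axis slicing axis, one of `"x"`, `"y"`, `"z"`.
#'
#' @seealso [medialSurface()], [commonSurface()]
#' @export
setClass("MedialSurface",
         representation(voxels = "matrix", axis = "character"))

setValidity("MedialSurface", function(object) {
    v <- object@voxels
    if (ncol(v) != 3L) return("'voxels' must have 3 columns")
    if (nrow(v) > 0L && (any(!is.finite(v)) || any(v != round(v))))
        return("'voxels' must be integer indices")
    if (!(object@axis %in% c("x", "y", "z")))
        return("'axis' must be one of 'x', 'y', 'z'")
    TRUE
})

#' Construct a MedialSurface
#'
#' @param voxels integer matrix (n x 3) of 0-based voxel indices.
#' @param axis slicing axis (`"x"`, `"y"` or `"z"`).
#' @return A [MedialSurface-class] object.
#' @export
MedialSurface <- function(voxels, axis) {
    voxels <- as.matrix(voxels)
    if (nrow(voxels) == 0L) voxels <- matrix(integer(), 0L, 3L)
    storage.mode(voxels) <- "integer"
    colnames(voxels) <- c("i", "j", "k")
    new("MedialSurface", voxels = voxels, axis = axis)
}

#' Intersection of medial surfaces
#'
#' Voxels common (up to a Chebyshev tolerance) to two or three per-axis
#' medial surfaces; the extraction method's centerline candidates.
#'
#' @slot voxels integer matrix (n x 3) of 0-based voxel indices.
#' @slot variant `"XY"`, `"YZ"`, `"XZ"` or `"XYZ"`.
#' @slot tolVoxels Chebyshev tolerance (voxels) used to form the set.
#'
#' @seealso [commonSurface()], [xyzCommon()], [orderPoints()]
#' @export
setClass("CommonPointSet",
         representation(voxels = "matrix", variant = "character",
                        tolVoxels = "integer"))

setValidity("CommonPointSet", function(object) {
    if (ncol(object@voxels) != 3L) return("'voxels' must have 3 columns")
    if (!(object@variant %in% c("XY", "YZ", "XZ", "XYZ")))
        return("'variant' must be XY, YZ, XZ or XYZ")
    if (length(object@tolVoxels) != 1L || object@tolVoxels < 0L)
        return("'tolVoxels' must be a single non-negative integer")
    TRUE
})

#' Construct a CommonPointSet
#'
#' @param voxels integer matrix (n x 3) of 0-based voxel indices.
#' @param variant one of `"XY"`, `"YZ"`, `"XZ"`, `"XYZ"`.
#' @param tolVoxels Chebyshev tolerance used when intersecting.
#' @return A [CommonPointSet-class] object.
#' @export
CommonPointSet <- function(voxels, variant, tolVoxels = 1L) {
    voxels <- as.matrix(voxels)
    if (nrow(voxels) == 0L) voxels <- matrix(integer(), 0L, 3L)
    storage.mode(voxels) <- "integer"
    colnames(voxels) <- c("i", "j", "k")
    new("CommonPointSet", voxels = voxels, variant = variant,
        tolVoxels = as.integer(tolVoxels))
}

#' Synthetic vessel specification
#'
#' Parameters of one parametric synthetic coronary vessel: class, length,
#' tapering radii, tortuosity and sampling. Class presets follow typical
#' coronary anatomy; see [phantomSpec()].
#'
#' @slot vesselClass `"RCA"`, `"LAD"`, `"LCX"` or `"BRANCH"`.
#' @slot length target centerline arc length (mm).
#' @slot radiusStart,radiusEnd proximal/distal lumen radius (mm); the radius
#'   tapers linearly in arc length.
#' @slot tortuosity dimensionless amplitude of the smooth 3D perturbation
#'   (lateral amplitude approximately `tortuosity * length`).
#' @slot sampleSpacing spacing between centerline samples (mm).
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec",
         representation(vesselClass = "character", length = "numeric",
                        radiusStart = "numeric", radiusEnd = "numeric",
                        tortuosity = "numeric", sampleSpacing = "numeric",
                        seed = "integer"))

setValidity("PhantomSpec", function(object) {
    if (!(object@vesselClass %in% c("RCA", "LAD", "LCX", "BRANCH")))
        return("'vesselClass' must be RCA, LAD, LCX or BRANCH")
    if (object@length <= 0) return("'length' must be > 0 mm")
    if (object@radiusStart <= 0 || object@radiusEnd <= 0)
        return("radii must be > 0 mm")
    if (object@tortuosity < 0) return("'tortuosity' must be >= 0")
    if (object@sampleSpacing <= 0) return("'sampleSpacing' must be > 0 mm")
    TRUE
})

#' Classification counts behind one overlap metric
#'
#' True-positive/false counts from the radius-thresholded nearest-neighbour
#' classification: `tpm`/`fp` label the evaluated (extracted) points,
#' `tpr`/`fn` label the reference points.
#'
#' @slot tpm,fp,tpr,fn integer counts.
#' @slot scope metric scope (`"OV"`, `"OF"` or `"OT"`).
#' @export
setClass("MetricCounts",
         representation(tpm = "integer", fp = "integer", tpr = "integer",
                        fn = "integer", scope = "character"))

#' Construct a MetricCounts
#'
#' @param tpm,fp,tpr,fn integer counts.
#' @param scope metric scope (`"OV"`, `"OF"` or `"OT"`).
#' @return A [MetricCounts-class] object.
#' @export
MetricCounts <- function(tpm, fp, tpr, fn, scope = "OV") {
    new("MetricCounts", tpm = as.integer(tpm), fp = as.integer(fp),
        tpr = as.integer(tpr), fn = as.integer(fn), scope = scope)
}

#' Centerline accuracy report
#'
#' The four standardized coronary centerline tracking accuracy measures for
#' one extracted/reference pair: total overlap (OV, %), overlap until first
#' error (OF, %), overlap of the clinically relevant portion (OT, %, `NA`
#' when no portion of the reference has diameter above the clinical
#' threshold) and average inside distance (AI, mm, `NA` when no point was
#' matched), plus the underlying counts.
#'
#' @slot ov,of,ot numeric percentages in `[0, 100]` (`ot` may be `NA`).
#' @slot ai mean matched distance in mm (may be `NA`).
#' @slot counts list of per-scope count information.
#' @slot nSamples resample count used for the evaluation.
#' @seealso [evaluateCenterline()]
#' @export
setClass("MetricReport",
         representation(ov = "numeric", of = "numeric", ot = "numeric",
                        ai = "numeric", counts = "list",
                        nSamples = "integer"))

setValidity("MetricReport", function(object) {
    for (s in c("ov", "of", "ot")) {
        v <- slot(object, s)
        if (!is.na(v) && (v < 0 || v > 100 + 1e-9))
            return(sprintf("'%s' must lie in [0, 100]", s))
    }
    if (!is.na(object@ai) && object@ai < 0)
        return("'ai' must be >= 0")
    TRUE
})
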