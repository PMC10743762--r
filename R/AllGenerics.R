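#' Accessors for VoronoiTrack objects
#'
#' Small accessor generics: `centerlinePoints()` returns the coordinate
#' matrix of a centerline, `radii()` the per-point radii of a reference,
#' `vesselLabel()` its identifier, `arcLengths()` the cumulative arc length
#' of an extracted centerline, `volumeGrid()`/`voxelSize()`/`volumeOrigin()`
#' the parts of a [BinaryVolume-class], `voxels()` the voxel index matrix of
#' a medial surface or common point set, `slicingAxis()` the source axis of
#' a [MedialSurface-class], `variantName()` the intersection variant of a
#' [CommonPointSet-class], and `metricValues()` the named OV/OF/OT/AI vector
#' of a [MetricReport-class].
#'
#' @param x an object of the appropriate class.
#' @return See the description of each accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("centerlinePoints", function(x) standardGeneric("centerlinePoints"))

#' @rdname accessors
#' @export
setGeneric("radii", function(x) standardGeneric("radii"))

#' @rdname accessors
#' @export
setGeneric("vesselLabel", function(x) standardGeneric("vesselLabel"))

#' @rdname accessors
#' @export
setGeneric("arcLengths", function(x) standardGeneric("arcLengths"))

#' @rdname accessors
#' @export
setGeneric("volumeGrid", function(x) standardGeneric("volumeGrid"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("volumeOrigin", function(x) standardGeneric("volumeOrigin"))

#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname accessors
#' @export
setGeneric("slicingAxis", function(x) standardGeneric("slicingAxis"))

#' @rdname accessors
#' @export
setGeneric("variantName", function(x) standardGeneric("variantName"))

#' @rdname accessors
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))
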