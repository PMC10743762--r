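#' @rdname accessors
setMethod("centerlinePoints", "ReferenceCenterline",
          function(x) x@points[, 1:3, drop = FALSE])

#' @rdname accessors
setMethod("centerlinePoints", "Centerline", function(x) x@points)

#' @rdname accessors
setMethod("radii", "ReferenceCenterline", function(x) x@points[, 4L])

#' @rdname accessors
setMethod("vesselLabel", "ReferenceCenterline", function(x) x@label)

#' @rdname accessors
setMethod("arcLengths", "Centerline", function(x) x@arcLengths)

#' @rdname accessors
setMethod("volumeGrid", "BinaryVolume", function(x) x@grid)

#' @rdname accessors
setMethod("voxelSize", "BinaryVolume", function(x) x@voxelSize)

#' @rdname accessors
setMethod("volumeOrigin", "BinaryVolume", function(x) x@origin)

#' @rdname accessors
setMethod("voxels", "MedialSurface", function(x) x@voxels)

#' @rdname accessors
setMethod("voxels", "CommonPointSet", function(x) x@voxels)

#' @rdname accessors
setMethod("slicingAxis", "MedialSurface", function(x) x@axis)

#' @rdname accessors
setMethod("variantName", "CommonPointSet", function(x) x@variant)

#' @rdname accessors
setMethod("metricValues", "MetricReport", function(x)
    c(OV = x@ov, OF = x@of, OT = x@ot, AI = x@ai))

setMethod("show", "ReferenceCenterline", function(object) {
    p <- object@points
    cat(sprintf("ReferenceCenterline '%s': %d points, length %.2f mm, radius %.2f-%.2f mm\n",
                object@label, nrow(p),
                sum(sqrt(rowSums(diff(p[, 1:3, drop = FALSE])^2))),
                min(p[, 4L]), max(p[, 4L])))
    invisible(object)
})

setMethod("show", "BinaryVolume", function(object) {
    d <- dim(object@grid)
    cat(sprintf("BinaryVolume: %d x %d x %d voxels @ %.3g mm, origin (%.2f, %.2f, %.2f) mm, %d foreground\n",
                d[1L], d[2L], d[3L], object@voxelSize,
                object@origin[1L], object@origin[2L], object@origin[3L],
                sum(object@grid)))
    invisible(object)
})

setMethod("show", "Centerline", function(object) {
    cat(sprintf("Centerline: %d points, length %.2f mm\n",
                nrow(object@points), max(object@arcLengths)))
    invisible(object)
})

setMethod("show", "MedialSurface", function(object) {
    cat(sprintf("MedialSurface (axis %s): %d voxels\n",
                object@axis, nrow(object@voxels)))
    invisible(object)
})

setMethod("show", "CommonPointSet", function(object) {
    cat(sprintf("CommonPointSet (%s-common, tol %d): %d voxels\n",
                object@variant, object@tolVoxels, nrow(object@voxels)))
    invisible(object)
})

setMethod("show", "PhantomSpec", function(object) {
    cat(sprintf("PhantomSpec %s: length %.1f mm, radius %.2f -> %.2f mm, tortuosity %.3f, spacing %.2f mm, seed %d\n",
                object@vesselClass, object@length, object@radiusStart,
                object@radiusEnd, object@tortuosity, object@sampleSpacing,
                object@seed))
    invisible(object)
})

setMethod("show", "MetricCounts", function(object) {
    cat(sprintf("MetricCounts (%s): TPM %d, FP %d, TPR %d, FN %d\n",
                object@scope, object@tpm, object@fp, object@tpr, object@fn))
    invisible(object)
})

setMethod("show", "MetricReport", function(object) {
    fmt <- function(v, unit) if (is.na(v)) "n/a" else sprintf("%.2f%s", v, unit)
    cat(sprintf("MetricReport (n = %d):\n", object@nSamples))
    cat(sprintf("  OV %s  OF %s  OT %s  AI %s\n",
                fmt(object@ov, "%"), fmt(object@of, "%"),
                fmt(object@ot, "%"),
                if (is.na(object@ai)) "n/a" else sprintf("%.3f mm", object@ai)))
    invisible(object)
})
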