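# Stacking per-slice 2D skeletons into per-axis medial surfaces and
# intersecting them (with a Chebyshev voxel tolerance) into the XY-, YZ-,
# XZ- and XYZ-common candidate centerline sets.

# encode (i,j,k) voxel indices as a single double (exact below 2^20 per axis)
.voxelKey <- function(v) {
    v[, 1L] + v[, 2L] * 2^20 + v[, 3L] * 2^40
}

#' Medial surface of a volume along one slicing axis
#'
#' Runs the 2D Voronoi skeleton on every slice perpendicular to `axis`,
#' snaps the in-plane skeleton points to their nearest voxel (half away
#' from zero, the package-wide tie rule) and unions the results across
#' slices. Slices without foreground are skipped.
#'
#' @param vol a [BinaryVolume-class].
#' @param axis slicing axis: `"x"`, `"y"` or `"z"`.
#' @param pruneRatio,smoothWindow passed to [voronoiSkeleton()].
#' @return A [MedialSurface-class] (0-based voxel indices).
#' @export
medialSurface <- function(vol, axis = c("x", "y", "z"), pruneRatio = 0.5,
                          smoothWindow = 2) {
    axis <- match.arg(axis)
    g <- vol@grid
    d <- dim(g)
    counts <- switch(axis,
        x = rowSums(g, dims = 1L),
        y = rowSums(colSums(g)),        # sum over i, then over k
        z = colSums(g, dims = 2L))
    nSlices <- switch(axis, x = d[1L], y = d[2L], z = d[3L])
    acc <- vector("list", nSlices)
    for (s in seq_len(nSlices)) {
        if (counts[s] == 0L) next
        m <- switch(axis,
                    x = g[s, , , drop = TRUE],
                    y = g[, s, , drop = TRUE],
                    z = g[, , s, drop = TRUE])
        sk <- voronoiSkeleton(m, pruneRatio = pruneRatio,
                              smoothWindow = smoothWindow)
        if (nrow(sk) == 0L) next
        a <- pmin(pmax(roundHalfAway(sk[, 1L]), 1), nrow(m))
        b <- pmin(pmax(roundHalfAway(sk[, 2L]), 1), ncol(m))
        keep <- m[cbind(a, b)] == 1L   # defensive: snapped pixel foreground
        if (!any(keep)) next
        a <- a[keep]; b <- b[keep]
        vox <- switch(axis,
                      x = cbind(s, a, b),
                      y = cbind(a, s, b),
                      z = cbind(a, b, s)) - 1L
        acc[[s]] <- unique(vox)
    }
    vox <- do.call(rbind, acc)
    if (is.null(vox)) vox <- matrix(integer(), 0L, 3L)
    MedialSurface(unique(vox), axis = axis)
}

# rows of 'a' voxels with some voxel of keysB within Chebyshev distance tol
.nearSet <- function(a, keysB, tol) {
    if (nrow(a) == 0L) return(logical(0L))
    if (tol == 0L) return(.voxelKey(a) %in% keysB)
    near <- rep(FALSE, nrow(a))
    for (di in -tol:tol) for (dj in -tol:tol) for (dk in -tol:tol) {
        idx <- which(!near)
        if (length(idx) == 0L) return(near)
        k <- (a[idx, 1L] + di) + (a[idx, 2L] + dj) * 2^20 +
             (a[idx, 3L] + dk) * 2^40
        near[idx[k %in% keysB]] <- TRUE
    }
    near
}

#' Intersect two medial surfaces
#'
#' Returns the voxels of `a` lying within `tolVoxels` (Chebyshev) of some
#' voxel of `b`, united with the symmetric selection from `b`. The
#' tolerance absorbs the independent quantization of skeleton points from
#' different slicing directions; `tolVoxels = 0` is exact set intersection.
#'
#' @param a,b [MedialSurface-class] objects from the same volume, with
#'   different slicing axes.
#' @param tolVoxels non-negative integer Chebyshev tolerance.
#' @return A [CommonPointSet-class] (variant `"XY"`, `"YZ"` or `"XZ"`,
#'   named from the two source axes).
#' @export
commonSurface <- function(a, b, tolVoxels = 1L) {
    stopifnot(is(a, "MedialSurface"), is(b, "MedialSurface"))
    if (a@axis == b@axis)
        stop("commonSurface needs surfaces from two different slicing axes")
    tolVoxels <- as.integer(tolVoxels)
    variant <- paste(toupper(sort(c(a@axis, b@axis))), collapse = "")
    variant <- c(XY = "XY", YZ = "YZ", XZ = "XZ")[[variant]]
    selA <- .nearSet(a@voxels, .voxelKey(b@voxels), tolVoxels)
    selB <- .nearSet(b@voxels, .voxelKey(a@voxels), tolVoxels)
    vox <- unique(rbind(a@voxels[selA, , drop = FALSE],
                        b@voxels[selB, , drop = FALSE]))
    CommonPointSet(vox, variant = variant, tolVoxels = tolVoxels)
}

#' Intersect all three medial surfaces
#'
#' As [commonSurface()], but a voxel is kept iff it lies within the
#' tolerance of both *other* surfaces; the union over the three source
#' surfaces is returned (variant `"XYZ"`).
#'
#' @param xs,ys,zs the three per-axis [MedialSurface-class] objects.
#' @param tolVoxels non-negative integer Chebyshev tolerance.
#' @return A [CommonPointSet-class] with variant `"XYZ"`.
#' @export
xyzCommon <- function(xs, ys, zs, tolVoxels = 1L) {
    surfs <- list(xs, ys, zs)
    axes <- vapply(surfs, function(s) s@axis, character(1L))
    if (!setequal(axes, c("x", "y", "z")))
        stop("xyzCommon needs one surface per slicing axis")
    tolVoxels <- as.integer(tolVoxels)
    keys <- lapply(surfs, function(s) .voxelKey(s@voxels))
    sel <- vector("list", 3L)
    for (i in 1:3) {
        others <- setdiff(1:3, i)
        v <- surfs[[i]]@voxels
        ok <- .nearSet(v, keys[[others[1L]]], tolVoxels) &
              .nearSet(v, keys[[others[2L]]], tolVoxels)
        sel[[i]] <- v[ok, , drop = FALSE]
    }
    CommonPointSet(unique(do.call(rbind, sel)), variant = "XYZ",
                   tolVoxels = tolVoxels)
}
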