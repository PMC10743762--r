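# Rounding and voxel/world coordinate maps. One tie rule everywhere:
# round half away from zero.

#' Round half away from zero
#'
#' Symmetric rounding used throughout the package (centerline rounding,
#' skeleton snapping, world-to-voxel maps), so 0.5 -> 1 and -0.5 -> -1,
#' unlike [base::round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits decimal digits to keep.
#' @return Rounded numeric vector.
#' @export
roundHalfAway <- function(x, digits = 0) {
    s <- 10^digits
    sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

#' Map voxel indices to world coordinates and back
#'
#' Voxel centers carry the world (mm) coordinates:
#' `voxelToMm(i) = origin + i * voxelSize` with 0-based indices, and
#' `mmToVoxel()` rounds to the nearest voxel center (ties half away from
#' zero). The two maps are mutually inverse on voxel centers.
#'
#' @param index integer vector of length 3, or an n x 3 matrix (0-based).
#' @param vol a [BinaryVolume-class].
#' @return `voxelToMm()`: mm coordinates (same shape as input).
#' @export
voxelToMm <- function(index, vol) {
    h <- vol@voxelSize
    if (is.matrix(index))
        sweep(index * h, 2L, vol@origin, "+")
    else
        vol@origin + index * h
}

#' @rdname voxelToMm
#' @param mm numeric vector of length 3, or an n x 3 matrix of mm coordinates.
#' @return `mmToVoxel()`: 0-based voxel indices; positions outside the grid
#'   raise an error.
#' @export
mmToVoxel <- function(mm, vol) {
    h <- vol@voxelSize
    if (is.matrix(mm))
        idx <- roundHalfAway(sweep(mm, 2L, vol@origin, "-") / h)
    else
        idx <- roundHalfAway((mm - vol@origin) / h)
    d <- dim(vol@grid)
    bad <- if (is.matrix(idx)) {
        idx[, 1L] < 0 | idx[, 1L] >= d[1L] |
        idx[, 2L] < 0 | idx[, 2L] >= d[2L] |
        idx[, 3L] < 0 | idx[, 3L] >= d[3L]
    } else {
        any(idx < 0 | idx >= d)
    }
    if (any(bad))
        stop("mmToVoxel: position outside the volume grid")
    storage.mode(idx) <- "integer"
    idx
}
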