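# Reading/writing centerline text files and NIfTI volumes. This file owns
# all coordinate conventions: units are mm everywhere, voxel centers carry
# world coordinates, array axes (i, j, k) map to world (x, y, z) with no
# permutation, and only axis-aligned positive-scale isotropic affines are
# accepted (this tool does not reorient).

#' Read a reference centerline file
#'
#' Parses a plain-text centerline file with one point per line:
#' `x y z r` (mm), whitespace-separated. Comment lines starting with `#`
#' and empty lines are skipped; extra columns are ignored.
#'
#' @param path file path.
#' @param label identifier to attach; defaults to the file name without
#'   extension.
#' @return A [ReferenceCenterline-class].
#' @export
readReference <- function(path, label = NULL) {
    if (!file.exists(path))
        stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    keep <- !grepl("^\\s*(#|$)", lines)
    idx <- which(keep)
    if (length(idx) < 2L)
        stop("invalid centerline: fewer than 2 points in ", path)
    pts <- matrix(NA_real_, length(idx), 4L)
    for (n in seq_along(idx)) {
        fields <- strsplit(trimws(lines[idx[n]]), "\\s+")[[1L]]
        if (length(fields) < 4L)
            stop(sprintf("parse error at line %d of %s: expected at least 4 fields",
                         idx[n], path))
        vals <- suppressWarnings(as.numeric(fields[1:4]))
        if (any(is.na(vals)))
            stop(sprintf("parse error at line %d of %s: non-numeric field",
                         idx[n], path))
        pts[n, ] <- vals
    }
    if (is.null(label))
        label <- sub("\\.[^.]*$", "", basename(path))
    ReferenceCenterline(pts, label = label)
}

#' Write a reference centerline file
#'
#' One `x y z r` line per point, full double precision.
#'
#' @param ref a [ReferenceCenterline-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeReference <- function(ref, path) {
    stopifnot(is(ref, "ReferenceCenterline"))
    p <- ref@points
    con <- file(path, "wb")  # binary: fixed '\n', byte-identical across runs
    on.exit(close(con))
    writeLines(c(paste0("# ", ref@label),
                 sprintf("%.10g %.10g %.10g %.10g",
                         p[, 1L], p[, 2L], p[, 3L], p[, 4L])),
               con, sep = "\n")
    invisible(path)
}

#' Write an extracted centerline file
#'
#' One `x y z` mm triple per line (no radius column).
#'
#' @param line a [Centerline-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeCenterline <- function(line, path) {
    stopifnot(is(line, "Centerline"))
    p <- line@points
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(sprintf("%.10g %.10g %.10g", p[, 1L], p[, 2L], p[, 3L]),
               con, sep = "\n")
    invisible(path)
}

#' Read a binary segmentation volume (NIfTI)
#'
#' Values different from zero are binarized to 1. The voxel size and world
#' origin are taken from the NIfTI affine, which must be axis-aligned with
#' positive isotropic scales; anything else raises an error (this tool does
#' not reorient). NIfTI stores spatial header fields as 32-bit floats, so
#' scales/origins are snapped back to 7 significant digits on read.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return A [BinaryVolume-class].
#' @export
readVolume <- function(path) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L)
        stop("unsupported volume: expected 3D, got ", length(d), "D")
    aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
    rot <- aff[1:3, 1:3]
    off <- rot - diag(diag(rot))
    if (any(abs(off) > 1e-5 * max(abs(diag(rot)))))
        stop("unsupported orientation: affine is not axis-aligned")
    scales <- diag(rot)
    if (any(scales <= 0))
        stop("unsupported orientation: negative or zero affine scales")
    if (diff(range(scales)) > 1e-5 * mean(scales))
        stop("unsupported volume: anisotropic voxels")
    h <- signif(mean(scales), 7)
    origin <- signif(aff[1:3, 4L], 7)
    BinaryVolume(img[] != 0, voxelSize = h, origin = origin)
}

#' Write a binary segmentation volume (NIfTI)
#'
#' Writes the 0/1 grid as uint8 with a diagonal sform affine carrying the
#' voxel size and origin.
#'
#' @param vol a [BinaryVolume-class].
#' @param path output `.nii` or `.nii.gz` path.
#' @return Invisibly, `path`.
#' @export
writeVolume <- function(vol, path) {
    stopifnot(is(vol, "BinaryVolume"))
    aff <- diag(c(rep(vol@voxelSize, 3L), 1))
    aff[1:3, 4L] <- vol@origin
    img <- RNifti::asNifti(vol@grid)
    img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
    RNifti::writeNifti(img, path, datatype = "uint8")
    invisible(path)
}
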