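# End-to-end harness: extract all requested centerline variants from each
# volume of a manifest, evaluate against the references, and summarize
# per vessel, per vessel class and overall.

#' Extract a centerline from a binary volume
#'
#' The full divide-and-conquer pipeline for one volume: per-axis medial
#' surfaces (2D Voronoi skeletons stacked along each slicing direction),
#' intersection into the requested common variant, ordering via the
#' minimum-spanning-tree diameter path, and optional uniform resampling.
#'
#' @param vol a [BinaryVolume-class].
#' @param variant `"XY"`, `"YZ"`, `"XZ"` or `"XYZ"`.
#' @param tolVoxels Chebyshev intersection tolerance (voxels).
#' @param pruneRatio relative clearance pruning threshold for the 2D
#'   skeletons.
#' @param nSamples resample count; `NA` to return the un-resampled path.
#' @return A [Centerline-class].
#' @export
extractCenterline <- function(vol, variant = c("XYZ", "XY", "YZ", "XZ"),
                              tolVoxels = 1L, pruneRatio = 0.5,
                              nSamples = 1000L) {
    variant <- match.arg(variant)
    axes <- switch(variant, XY = c("x", "y"), YZ = c("y", "z"),
                   XZ = c("x", "z"), XYZ = c("x", "y", "z"))
    surfs <- lapply(axes, function(ax)
        medialSurface(vol, ax, pruneRatio = pruneRatio))
    common <- if (variant == "XYZ")
        xyzCommon(surfs[[1L]], surfs[[2L]], surfs[[3L]], tolVoxels = tolVoxels)
    else
        commonSurface(surfs[[1L]], surfs[[2L]], tolVoxels = tolVoxels)
    line <- orderPoints(common, vol)
    if (is.na(nSamples)) line else resampleCenterline(line, n = nSamples)
}

# variant -> required slicing axes
.variantAxes <- function(variants) {
    ax <- unlist(lapply(variants, function(v) switch(v,
        XY = c("x", "y"), YZ = c("y", "z"), XZ = c("x", "z"),
        XYZ = c("x", "y", "z"))))
    unique(ax)
}

#' Run the phantom benchmark
#'
#' For every volume/reference pair in a manifest (as written by
#' [generateBenchmarkSet()]), extracts each requested centerline variant
#' and evaluates it against the reference, then aggregates: one row per
#' vessel and variant, mean rows per vessel class, and grand means per
#' variant. Vessels failing extraction are recorded with an error message,
#' not dropped. Deterministic given the manifest and configuration.
#'
#' @param manifest path to a tab-separated manifest (`volume<TAB>reference`
#'   per line, paths relative to the manifest) or a data.frame with columns
#'   `volume` and `reference`.
#' @param variants subset of `c("XY", "YZ", "XZ", "XYZ")`.
#' @param tolVoxels,pruneRatio,nSamples pipeline configuration, see
#'   [extractCenterline()].
#' @param verbose print per-vessel progress to stderr.
#' @return A list with data.frames `perVessel` (dataset, vessel, variant,
#'   OV, OF, OT, AI, error), `perClass` (means per vessel class and
#'   variant) and `grand` (means per variant). OT/AI means skip
#'   not-applicable values.
#' @export
runBenchmark <- function(manifest, variants = c("XY", "YZ", "XZ", "XYZ"),
                         tolVoxels = 1L, pruneRatio = 0.5, nSamples = 1000L,
                         verbose = TRUE) {
    variants <- match.arg(variants, several.ok = TRUE)
    if (is.character(manifest)) {
        base <- dirname(manifest)
        man <- utils::read.table(manifest, sep = "\t", header = FALSE,
                                 stringsAsFactors = FALSE,
                                 col.names = c("volume", "reference"))
    } else {
        base <- "."
        man <- as.data.frame(manifest)
    }
    resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
    rows <- list()
    for (i in seq_len(nrow(man))) {
        volPath <- resolve(man$volume[i])
        refPath <- resolve(man$reference[i])
        ref <- readReference(refPath)
        id <- sub("\\.[^.]*$", "", basename(refPath))
        parts <- strsplit(id, "_")[[1L]]
        dataset <- sub("^dataset", "", parts[1L])
        vclass <- if (length(parts) > 1L) parts[2L] else id
        vol <- readVolume(volPath)
        surfs <- list()
        for (ax in .variantAxes(variants))
            surfs[[ax]] <- medialSurface(vol, ax, pruneRatio = pruneRatio)
        for (v in variants) {
            res <- tryCatch({
                common <- if (v == "XYZ")
                    xyzCommon(surfs$x, surfs$y, surfs$z, tolVoxels = tolVoxels)
                else {
                    ax <- .variantAxes(v)
                    commonSurface(surfs[[ax[1L]]], surfs[[ax[2L]]],
                                  tolVoxels = tolVoxels)
                }
                line <- orderPoints(common, vol)
                rep <- evaluateCenterline(line, ref, n = nSamples)
                data.frame(dataset = dataset, vessel = vclass, variant = v,
                           OV = rep@ov, OF = rep@of, OT = rep@ot,
                           AI = rep@ai, error = NA_character_,
                           stringsAsFactors = FALSE)
            }, error = function(e)
                data.frame(dataset = dataset, vessel = vclass, variant = v,
                           OV = NA_real_, OF = NA_real_, OT = NA_real_,
                           AI = NA_real_, error = conditionMessage(e),
                           stringsAsFactors = FALSE))
            rows[[length(rows) + 1L]] <- res
            if (verbose)
                message(sprintf("[%s %s %s] OV=%.2f OF=%.2f OT=%.2f AI=%.3f %s",
                                dataset, vclass, v, res$OV, res$OF, res$OT,
                                res$AI,
                                if (is.na(res$error)) "" else res$error))
        }
    }
    perVessel <- do.call(rbind, rows)
    agg <- function(df, by) {
        out <- stats::aggregate(df[, c("OV", "OF", "OT", "AI")], by = by,
                                FUN = function(x) mean(x, na.rm = TRUE))
        out
    }
    perClass <- agg(perVessel, list(vessel = perVessel$vessel,
                                    variant = perVessel$variant))
    grand <- agg(perVessel, list(variant = perVessel$variant))
    list(perVessel = perVessel, perClass = perClass, grand = grand)
}
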