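# Synthetic vessel phantoms: parametric centerlines for the four coronary
# vessel classes and union-of-spheres rasterization into binary volumes.

# Class presets (mm): lengths, proximal/distal radii and tortuosity chosen
# from typical coronary dimensions; see the methods vignette.
.phantomClassDefaults <- list(
    RCA    = list(length = 60, radiusStart = 2.70, radiusEnd = 1.10, tortuosity = 0.07),
    LAD    = list(length = 50, radiusStart = 2.00, radiusEnd = 0.80, tortuosity = 0.06),
    LCX    = list(length = 45, radiusStart = 1.85, radiusEnd = 0.75, tortuosity = 0.06),
    BRANCH = list(length = 25, radiusStart = 1.40, radiusEnd = 0.60, tortuosity = 0.04)
)

#' Create a synthetic vessel specification
#'
#' Returns a [PhantomSpec-class] for one of the four coronary vessel
#' classes (RCA, LAD, LCX, large side-branch). Unspecified parameters take
#' class presets reflecting typical coronary anatomy: lengths 25--60 mm,
#' linearly tapering radii 0.6--2.7 mm, smooth 3D tortuosity.
#'
#' @param vesselClass `"RCA"`, `"LAD"`, `"LCX"` or `"BRANCH"`.
#' @param length target centerline arc length (mm).
#' @param radiusStart,radiusEnd proximal and distal radius (mm).
#' @param tortuosity dimensionless amplitude of the smooth 3D perturbation;
#'   lateral amplitude is approximately `tortuosity * length`.
#' @param sampleSpacing spacing between generated centerline points (mm).
#' @param seed integer RNG seed (deterministic output for a fixed seed).
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(vesselClass = c("RCA", "LAD", "LCX", "BRANCH"),
                        length = NULL, radiusStart = NULL, radiusEnd = NULL,
                        tortuosity = NULL, sampleSpacing = 0.4, seed = 0L) {
    vesselClass <- match.arg(vesselClass)
    def <- .phantomClassDefaults[[vesselClass]]
    new("PhantomSpec",
        vesselClass = vesselClass,
        length = as.numeric(if (is.null(length)) def$length else length),
        radiusStart = as.numeric(if (is.null(radiusStart)) def$radiusStart else radiusStart),
        radiusEnd = as.numeric(if (is.null(radiusEnd)) def$radiusEnd else radiusEnd),
        tortuosity = as.numeric(if (is.null(tortuosity)) def$tortuosity else tortuosity),
        sampleSpacing = as.numeric(sampleSpacing),
        seed = as.integer(seed))
}

# evaluate an expression with a local RNG state
.withLocalSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Simulate a synthetic vessel centerline
#'
#' Generates a smooth (twice-differentiable) 3D curve of total arc length
#' `length(spec)`, sampled every `sampleSpacing` mm, with the radius
#' interpolating linearly from `radiusStart` to `radiusEnd`. The curve runs
#' along +x with low-frequency sinusoidal perturbations (two harmonics with
#' seeded random amplitudes and phases) in y and z; with `tortuosity = 0`
#' it is a straight +x segment. The local radius of curvature is verified
#' to exceed twice the maximum vessel radius everywhere, so the swept tube
#' cannot self-intersect; violating parameters raise an error reporting the
#' offending curvature.
#'
#' @param spec a [PhantomSpec-class].
#' @return A [ReferenceCenterline-class] (label = vessel class).
#' @export
simulateCenterline <- function(spec) {
    stopifnot(is(spec, "PhantomSpec"))
    validObject(spec)
    L <- spec@length
    amp0 <- spec@tortuosity * L
    pars <- .withLocalSeed(spec@seed, list(
        ay = amp0 * stats::runif(2L, 0.5, 1) / c(1, 4),
        az = amp0 * stats::runif(2L, 0.5, 1) / c(1, 4),
        py = stats::runif(2L, 0, 2 * pi),
        pz = stats::runif(2L, 0, 2 * pi)))

    nFine <- max(2000L, ceiling(40 * L / spec@sampleSpacing))
    t <- seq(0, L, length.out = nFine)
    w <- 2 * pi / L
    yk <- function(tt) pars$ay[1L] * sin(w * tt + pars$py[1L]) +
                       pars$ay[2L] * sin(2 * w * tt + pars$py[2L])
    zk <- function(tt) pars$az[1L] * sin(w * tt + pars$pz[1L]) +
                       pars$az[2L] * sin(2 * w * tt + pars$pz[2L])
    P <- cbind(x = t, y = yk(t), z = zk(t))

    # curvature from analytic derivatives of the parametrization
    d1 <- cbind(1,
                pars$ay[1L] * w * cos(w * t + pars$py[1L]) +
                pars$ay[2L] * 2 * w * cos(2 * w * t + pars$py[2L]),
                pars$az[1L] * w * cos(w * t + pars$pz[1L]) +
                pars$az[2L] * 2 * w * cos(2 * w * t + pars$pz[2L]))
    d2 <- cbind(0,
                -pars$ay[1L] * w^2 * sin(w * t + pars$py[1L]) -
                 pars$ay[2L] * 4 * w^2 * sin(2 * w * t + pars$py[2L]),
                -pars$az[1L] * w^2 * sin(w * t + pars$pz[1L]) -
                 pars$az[2L] * 4 * w^2 * sin(2 * w * t + pars$pz[2L]))
    cr <- cbind(d1[, 2L] * d2[, 3L] - d1[, 3L] * d2[, 2L],
                d1[, 3L] * d2[, 1L] - d1[, 1L] * d2[, 3L],
                d1[, 1L] * d2[, 2L] - d1[, 2L] * d2[, 1L])
    speed2 <- rowSums(d1^2)
    kappa <- sqrt(rowSums(cr^2)) / speed2^1.5
    rmax <- max(spec@radiusStart, spec@radiusEnd)
    kmax <- max(kappa)
    if (kmax > 0 && 1 / kmax <= 2 * rmax)
        stop(sprintf(paste0("self-intersecting tube: curvature radius %.2f mm ",
                            "<= 2 x max vessel radius %.2f mm"),
                     1 / kmax, rmax))

    # reparametrize by arc length and truncate at total length L
    arc <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
    s <- seq(0, L, by = spec@sampleSpacing)
    if (max(arc) < L)  # straight case: arc == t == L at the end
        s[length(s)] <- min(s[length(s)], max(arc))
    pts <- cbind(stats::approx(arc, P[, 1L], xout = s, ties = "ordered", rule = 2)$y,
                 stats::approx(arc, P[, 2L], xout = s, ties = "ordered", rule = 2)$y,
                 stats::approx(arc, P[, 3L], xout = s, ties = "ordered", rule = 2)$y,
                 spec@radiusStart + (spec@radiusEnd - spec@radiusStart) * s / L)
    ReferenceCenterline(pts, label = spec@vesselClass)
}

#' Round a centerline to a fixed decimal precision
#'
#' Rounds every coordinate and radius (half away from zero) and collapses
#' points whose rounded (x, y, z) coincide with the previous point, exactly
#' as the union-of-spheres rasterizer expects. Idempotent.
#'
#' @param ref a [ReferenceCenterline-class].
#' @param decimals decimal digits to keep (default 1, i.e. 0.1 mm).
#' @return A rounded [ReferenceCenterline-class].
#' @export
roundCenterline <- function(ref, decimals = 1L) {
    stopifnot(is(ref, "ReferenceCenterline"))
    p <- roundHalfAway(ref@points, digits = decimals)
    dup <- c(FALSE, rowSums(abs(diff(p[, 1:3, drop = FALSE]))) == 0)
    ReferenceCenterline(p[!dup, , drop = FALSE], label = ref@label)
}

#' Rasterize a centerline as a union of spheres
#'
#' Builds the binary tube volume of a centerline: a voxel is foreground iff
#' its center lies within (closed inequality) distance `r_p` of at least
#' one centerline point `p` (solid balls). The bounding box covers every
#' sphere plus `margin` mm on all sides; the grid origin is snapped to the
#' voxel lattice anchored at the world origin, so coordinates rounded to the
#' voxel size land exactly on voxel centers.
#'
#' @param ref a [ReferenceCenterline-class], normally pre-rounded with
#'   [roundCenterline()] to the voxel precision.
#' @param voxelSize voxel edge length in mm.
#' @param margin padding in mm (must be at least the maximum radius;
#'   default exactly that).
#' @param voxelBudget refuse (before allocation) to build grids larger than
#'   this many voxels.
#' @return A [BinaryVolume-class].
#' @export
voxelizeSpheres <- function(ref, voxelSize = 0.1, margin = NULL,
                            voxelBudget = 5e8) {
    stopifnot(is(ref, "ReferenceCenterline"))
    p <- ref@points
    rmax <- max(p[, 4L])
    if (is.null(margin)) margin <- rmax
    if (margin < rmax)
        stop("'margin' must be at least the maximum radius (", rmax, " mm)")
    h <- voxelSize
    lo <- apply(p[, 1:3, drop = FALSE] - p[, 4L], 2L, min) - margin
    hi <- apply(p[, 1:3, drop = FALSE] + p[, 4L], 2L, max) + margin
    origin <- h * floor(lo / h + 1e-9)
    dims <- as.integer(ceiling((hi - origin) / h - 1e-9)) + 1L
    if (prod(as.numeric(dims)) > voxelBudget)
        stop(sprintf("predicted grid %d x %d x %d exceeds the voxel budget (%g)",
                     dims[1L], dims[2L], dims[3L], voxelBudget))
    grid <- .voxelize_spheres_cpp(p, origin, h, dims)
    dim(grid) <- dims
    new("BinaryVolume", grid = grid, voxelSize = h, origin = origin)
}

# deterministic per-vessel seed stream from (master seed, dataset, class)
.vesselSeed <- function(master, dataset, classIdx) {
    v <- as.numeric(master) %% 2147483647
    v <- (v * 48271 + as.numeric(dataset) * 9973 +
          as.numeric(classIdx) * 7919 + 12345) %% 2147483647
    as.integer(v)
}

#' Generate a benchmark set of synthetic vessels
#'
#' Writes `nDatasets` synthetic datasets of four vessels each (RCA, LAD,
#' LCX, BRANCH class presets), i.e. `4 * nDatasets` volume/reference pairs,
#' plus a manifest file. Per-vessel seeds are derived deterministically
#' from the master seed, so the same seed reproduces byte-identical
#' reference files. The reference file holds the simulated (unrounded)
#' centerline; the volume is rasterized from its copy rounded to the voxel
#' precision, mirroring how annotated ground truth relates to a synthetic
#' segmentation.
#'
#' @param nDatasets number of datasets (>= 1).
#' @param outDir output directory (created if missing).
#' @param seed master integer seed.
#' @param voxelSize voxel edge length in mm.
#' @return Invisibly, a data.frame with columns `volume` and `reference`
#'   (paths relative to `outDir`); also written as `manifest.tsv`.
#' @export
generateBenchmarkSet <- function(nDatasets, outDir, seed = 0L,
                                 voxelSize = 0.1) {
    stopifnot(nDatasets >= 1)
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory: ", outDir)
    classes <- c("RCA", "LAD", "LCX", "BRANCH")
    rows <- vector("list", nDatasets * 4L)
    n <- 0L
    for (d in seq_len(nDatasets) - 1L) {
        for (ci in seq_along(classes)) {
            cls <- classes[ci]
            spec <- phantomSpec(cls, seed = .vesselSeed(seed, d, ci))
            ref <- simulateCenterline(spec)
            ref@label <- sprintf("dataset%d_%s", d, cls)
            refFile <- sprintf("dataset%d_%s.txt", d, cls)
            volFile <- sprintf("dataset%d_%s.nii", d, cls)
            writeReference(ref, file.path(outDir, refFile))
            vol <- voxelizeSpheres(roundCenterline(ref), voxelSize = voxelSize)
            writeVolume(vol, file.path(outDir, volFile))
            n <- n + 1L
            rows[[n]] <- data.frame(volume = volFile, reference = refFile,
                                    stringsAsFactors = FALSE)
        }
    }
    manifest <- do.call(rbind, rows)
    utils::write.table(manifest, file.path(outDir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    invisible(manifest)
}
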