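# 2D Voronoi-based skeletonization of one binary slice. Pipeline per
# connected component: sub-pixel boundary contour at the 0.5 iso-level
# (marching squares), light circular smoothing to suppress pixelation
# staircase noise, densification to <= 1 px sample spacing, Delaunay
# triangulation of the boundary sites, and retention of the interior
# Voronoi vertices (triangle circumcenters) whose clearance survives the
# relative pruning threshold. Pixel centers sit at integer (u, v); all
# in-plane coordinates are 1-based like the mask matrix.

# circular moving average of a closed polyline (n x 2), window w samples
.smoothClosed <- function(pts, w) {
    n <- nrow(pts)
    if (w < 3L || n < 2L * w) return(pts)
    half <- w %/% 2L
    idx <- outer(seq_len(n), (-half):half, "+")
    idx <- ((idx - 1L) %% n) + 1L
    cbind(rowMeans(matrix(pts[idx, 1L], n)), rowMeans(matrix(pts[idx, 2L], n)))
}

# subdivide segments of a closed polyline so spacing <= maxStep
.densifyClosed <- function(pts, maxStep = 1) {
    n <- nrow(pts)
    nxt <- c(seq_len(n)[-1L], 1L)
    seg <- sqrt(rowSums((pts[nxt, , drop = FALSE] - pts)^2))
    reps <- pmax(1L, ceiling(seg / maxStep - 1e-9))
    if (all(reps == 1L)) return(pts)
    i <- rep(seq_len(n), reps)
    f <- (sequence(reps) - 1) / reps[i]
    cbind(pts[i, 1L] + f * (pts[nxt[i], 1L] - pts[i, 1L]),
          pts[i, 2L] + f * (pts[nxt[i], 2L] - pts[i, 2L]))
}

#' Extract sub-pixel boundary contours of a binary slice
#'
#' Traces the 0.5 iso-level of the mask (marching squares on the pixel
#' lattice, zero-padded so all contours close), applies a light circular
#' moving-average smoothing (over roughly `smoothWindow` px of arc) to
#' remove pixelation staircase noise, and densifies each contour so that
#' consecutive samples are at most 1 px apart. Pixel `(i, j)` has its
#' center at coordinates `(i, j)`.
#'
#' @param mask binary integer matrix (0/1).
#' @param smoothWindow smoothing extent in px of contour arc; 0 disables.
#' @return A list of closed contours, each an (m x 2) matrix of `(u, v)`
#'   coordinates whose first row is repeated as the last row. Empty mask:
#'   empty list.
#' @export
extractBoundary <- function(mask, smoothWindow = 2) {
    nr <- nrow(mask); nc <- ncol(mask)
    if (sum(mask) == 0L) return(list())
    pad <- matrix(0, nr + 2L, nc + 2L)
    pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
    cl <- grDevices::contourLines(x = 0:(nr + 1L), y = 0:(nc + 1L),
                                  z = pad, levels = 0.5)
    lapply(cl, function(co) {
        pts <- cbind(co$x, co$y)
        n <- nrow(pts)
        closed <- n > 1L && all(abs(pts[1L, ] - pts[n, ]) < 1e-9)
        if (closed) pts <- pts[-n, , drop = FALSE]
        if (smoothWindow > 0 && nrow(pts) >= 8L) {
            spacing <- mean(sqrt(rowSums(
                (pts[c(seq_len(nrow(pts))[-1L], 1L), , drop = FALSE] - pts)^2)))
            w <- 2L * floor(smoothWindow / spacing / 2) + 1L
            pts <- .smoothClosed(pts, w)
        }
        pts <- .densifyClosed(pts, 1)
        rbind(pts, pts[1L, , drop = FALSE])
    })
}

#' Voronoi skeleton of a binary slice
#'
#' Approximates the medial axis of each connected component of the slice
#' by the interior Voronoi vertices of its densified boundary samples. A
#' vertex is kept iff (a) its rounded pixel is foreground, (b) its
#' separation angle — the widest angle its defining boundary samples
#' subtend at the vertex — is at least `minAngleDeg` (the standard
#' angle-based medial-axis pruning criterion: true medial points see two
#' well-separated boundary contacts, whereas spurious vertices generated
#' by near-collinear samples of a single flat boundary arc see a narrow
#' one), and (c) its clearance (distance to the nearest boundary sample,
#' i.e. the Delaunay circumradius) survives scale-local pruning: the
#' vertex is dropped when another vertex whose clearance exceeds
#' `clearance / pruneRatio` lies within twice that larger clearance.
#' This prunes at `pruneRatio` times the *local* maximum clearance, so
#' boundary-noise spurs near a wide lumen are suppressed without erasing
#' the thin end of a tapering cross-section. Components with fewer than 4 boundary
#' samples (or none of whose Voronoi vertices survive) contribute their
#' pixel centroid, so that few-pixel vessel caps still yield a centerline
#' point.
#'
#' @param mask binary integer matrix (0/1).
#' @param pruneRatio relative clearance threshold in `[0, 1]`; 0 keeps all
#'   interior vertices.
#' @param smoothWindow passed to [extractBoundary()].
#' @param minAngleDeg separation-angle threshold in degrees.
#' @return An (n x 2) matrix of `(u, v)` skeleton point coordinates in
#'   continuous 1-based pixel units (0 rows for an empty slice).
#' @export
voronoiSkeleton <- function(mask, pruneRatio = 0.5, smoothWindow = 2,
                            minAngleDeg = 90) {
    storage.mode(mask) <- "integer"
    empty <- matrix(numeric(), 0L, 2L)
    if (sum(mask) == 0L) return(empty)
    lab <- .label_components_cpp(mask)
    ncomp <- max(lab)
    nr <- nrow(mask)
    out <- vector("list", ncomp)
    for (comp in seq_len(ncomp)) {
        flat <- which(lab == comp)
        ri <- ((flat - 1L) %% nr) + 1L
        ci <- ((flat - 1L) %/% nr) + 1L
        if (length(flat) <= 3L) {
            out[[comp]] <- matrix(c(mean(ri), mean(ci)), 1L, 2L)
            next
        }
        r0 <- min(ri); c0 <- min(ci)
        sub <- (lab[r0:max(ri), c0:max(ci), drop = FALSE] == comp) + 0L
        contours <- extractBoundary(sub, smoothWindow = smoothWindow)
        sites <- do.call(rbind, lapply(contours, function(co)
            co[-nrow(co), , drop = FALSE]))
        if (is.null(sites) || nrow(sites) < 4L) {
            out[[comp]] <- matrix(c(mean(ri), mean(ci)), 1L, 2L)
            next
        }
        # shift to global slice coordinates
        sites[, 1L] <- sites[, 1L] + (r0 - 1L)
        sites[, 2L] <- sites[, 2L] + (c0 - 1L)
        # tiny deterministic jitter to break exact cocircularity
        k <- seq_len(nrow(sites))
        jx <- (((k * 2654435761) %% 1021) / 1021 - 0.5) * 2e-4
        jy <- (((k * 1779033703 + 7) %% 1021) / 1021 - 0.5) * 2e-4
        vert <- .delaunay_vertices_cpp(sites[, 1L] + jx, sites[, 2L] + jy)
        if (nrow(vert) == 0L) {
            out[[comp]] <- matrix(c(mean(ri), mean(ci)), 1L, 2L)
            next
        }
        pu <- roundHalfAway(vert[, 1L])
        pv <- roundHalfAway(vert[, 2L])
        inside <- pu >= 1 & pu <= nr & pv >= 1 & pv <= ncol(mask)
        inside[inside] <- mask[cbind(pu[inside], pv[inside])] == 1L &
                          lab[cbind(pu[inside], pv[inside])] == comp
        inside <- inside & vert[, 4L] >= minAngleDeg
        if (!any(inside)) {
            out[[comp]] <- matrix(c(mean(ri), mean(ci)), 1L, 2L)
            next
        }
        cand <- vert[inside, , drop = FALSE]
        dominated <- .prune_dominated_cpp(cand[, 1L], cand[, 2L],
                                          cand[, 3L], pruneRatio)
        out[[comp]] <- cand[!dominated, 1:2, drop = FALSE]
    }
    res <- do.call(rbind, out)
    colnames(res) <- c("u", "v")
    res
}
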