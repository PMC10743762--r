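# Ordering an unordered common point set into a polyline (minimum spanning
# tree, longest geodesic path) and uniform arc-length resampling.

#' Order a common point set into a centerline polyline
#'
#' Builds a graph on the common voxels in world (mm) coordinates with edges
#' between pairs closer than `(2 * tolVoxels + 1)` voxel diagonals, takes
#' the minimum spanning tree of its largest connected component and returns
#' the tree's longest geodesic (diameter) path, ordered end to end. Stray
#' isolated voxels and short spurs are thereby dropped.
#'
#' @param common a non-empty [CommonPointSet-class].
#' @param vol the source [BinaryVolume-class] (for voxel size and origin).
#' @return A [Centerline-class].
#' @export
orderPoints <- function(common, vol) {
    stopifnot(is(common, "CommonPointSet"), is(vol, "BinaryVolume"))
    v <- common@voxels
    if (nrow(v) == 0L)
        stop("empty extraction: the common point set has no voxels")
    if (nrow(v) == 1L)
        stop("degenerate extraction: a single common voxel cannot form a path")
    h <- vol@voxelSize
    P <- voxelToMm(v, vol)
    maxChebyshev <- ceiling((2 * common@tolVoxels + 1) * sqrt(3) - 1e-9)
    radius <- (2 * common@tolVoxels + 1) * sqrt(3) * h

    # neighbor search on the voxel lattice via hashed offset lookups
    keys <- .voxelKey(v)
    ord <- order(keys)
    keysSorted <- keys[ord]
    from <- integer(0L); to <- integer(0L)
    offs <- expand.grid(di = -maxChebyshev:maxChebyshev,
                        dj = -maxChebyshev:maxChebyshev,
                        dk = 0:maxChebyshev)
    offs <- offs[offs$dk > 0L | offs$dj > 0L |
                 (offs$dj == 0L & offs$dk == 0L & offs$di > 0L), ]  # half-space
    offs <- offs[sqrt(offs$di^2 + offs$dj^2 + offs$dk^2) * h <= radius + 1e-12, ]
    for (r in seq_len(nrow(offs))) {
        k <- keys + offs$di[r] + offs$dj[r] * 2^20 + offs$dk[r] * 2^40
        m <- findInterval(k, keysSorted)
        hit <- m > 0L & keysSorted[pmax(m, 1L)] == k
        if (any(hit)) {
            from <- c(from, which(hit))
            to <- c(to, ord[m[hit]])
        }
    }
    if (length(from) == 0L)
        stop("degenerate extraction: no two common voxels are adjacent")
    w <- sqrt(rowSums((P[from, , drop = FALSE] - P[to, , drop = FALSE])^2))
    g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
    g <- igraph::set_edge_attr(g, "weight", value = w)
    if (igraph::vcount(g) < nrow(v))
        g <- igraph::add_vertices(g, nrow(v) - igraph::vcount(g))
    comp <- igraph::components(g)
    keep <- which(comp$membership == which.max(comp$csize))
    sub <- igraph::induced_subgraph(g, keep)
    tree <- igraph::mst(sub)
    path <- igraph::get_diameter(tree)
    idx <- keep[as.integer(path)]
    if (length(idx) < 2L)
        stop("degenerate extraction: longest path has fewer than 2 points")
    Centerline(P[idx, , drop = FALSE])
}

#' Resample a centerline to uniformly spaced points
#'
#' Piecewise-linear interpolation of the polyline at arc lengths
#' `k * L / (n - 1)`, `k = 0 .. n-1`; the first and last points are
#' preserved exactly.
#'
#' @param line a [Centerline-class].
#' @param n number of output points (>= 2); 1000 is the standard
#'   evaluation resolution.
#' @return A resampled [Centerline-class].
#' @export
resampleCenterline <- function(line, n = 1000L) {
    stopifnot(is(line, "Centerline"), n >= 2L)
    arc <- line@arcLengths
    L <- arc[length(arc)]
    if (L <= 0)
        stop("cannot resample a zero-length centerline")
    s <- seq(0, L, length.out = n)
    p <- line@points
    out <- cbind(stats::approx(arc, p[, 1L], xout = s, ties = "ordered", rule = 2)$y,
                 stats::approx(arc, p[, 2L], xout = s, ties = "ordered", rule = 2)$y,
                 stats::approx(arc, p[, 3L], xout = s, ties = "ordered", rule = 2)$y)
    out[1L, ] <- p[1L, ]
    out[n, ] <- p[nrow(p), ]
    Centerline(out)
}
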