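# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately take the slow, direct route (exhaustive
# scans, double loops) so that they share no code path with the package.

# exhaustive union-of-spheres: test every voxel center against every ball
bruteBallGrid <- function(ref, vol) {
    g <- volumeGrid(vol)
    d <- dim(g)
    h <- voxelSize(vol)
    or <- volumeOrigin(vol)
    p <- cbind(centerlinePoints(ref), radii(ref))
    out <- array(0L, d)
    for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) for (k in seq_len(d[3L])) {
        cx <- or[1L] + (i - 1) * h
        cy <- or[2L] + (j - 1) * h
        cz <- or[3L] + (k - 1) * h
        for (q in seq_len(nrow(p))) {
            # associate as dx^2 + (dy^2 + dz^2): on exact-tie voxels the
            # closed inequality must not flip on the last ulp
            if ((cx - p[q, 1L])^2 + ((cy - p[q, 2L])^2 + (cz - p[q, 3L])^2) <=
                p[q, 4L]^2) {
                out[i, j, k] <- 1L
                break
            }
        }
    }
    out
}

# exact Euclidean distance transform of a 2D mask: per foreground pixel,
# distance to the nearest background pixel center (image border counts as
# background just outside the mask)
bruteEDT <- function(mask) {
    nr <- nrow(mask); nc <- ncol(mask)
    pad <- matrix(0L, nr + 2L, nc + 2L)
    pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
    fg <- which(pad == 1L, arr.ind = TRUE)
    bg <- which(pad == 0L, arr.ind = TRUE)
    d2 <- outer(fg[, 1L]^2 + fg[, 2L]^2, bg[, 1L]^2 + bg[, 2L]^2, "+") -
        2 * tcrossprod(fg, bg)
    dmin <- sqrt(pmax(apply(d2, 1L, min), 0))
    out <- matrix(0, nr + 2L, nc + 2L)
    out[fg] <- dmin
    out[2:(nr + 1L), 2:(nc + 1L)]
}

# ridge pixels of an EDT: foreground pixels that are a strict local maximum
# along some direction pair (N-S, E-W, or either diagonal). A plain
# "maximum over all 8 neighbours" is degenerate here: the EDT slopes along
# the medial line of any shape of varying width, so all-neighbour maxima
# reduce to a handful of peak pixels and cannot trace the ridge.
edtRidge <- function(edt, mask) {
    nr <- nrow(edt); nc <- ncol(edt)
    ridge <- matrix(FALSE, nr, nc)
    dirs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
        if (mask[i, j] == 0L) next
        for (d in dirs) {
            ni <- i + d[1L]; nj <- j + d[2L]
            pi <- i - d[1L]; pj <- j - d[2L]
            up <- if (ni < 1L || ni > nr || nj < 1L || nj > nc) 0 else edt[ni, nj]
            dn <- if (pi < 1L || pi > nr || pj < 1L || pj > nc) 0 else edt[pi, pj]
            e <- edt[i, j]
            # <= on both sides with at least one strict: rides over the
            # 2-px plateaus that even-width strips produce in the EDT
            if (up <= e && dn <= e && (up < e || dn < e)) {
                ridge[i, j] <- TRUE; break
            }
        }
    }
    which(ridge, arr.ind = TRUE)
}

# random union-of-disks blob mask on an n x n grid; disks are chained so
# the blob is a single connected component
randomBlobMask <- function(n = 48L, nDisks = 3L, seed = 1L) {
    set.seed(seed)
    m <- matrix(0L, n, n)
    cx <- runif(1, n * 0.4, n * 0.6)
    cy <- runif(1, n * 0.4, n * 0.6)
    r <- runif(1, n * 0.12, n * 0.2)
    for (q in seq_len(nDisks)) {
        for (i in seq_len(n)) for (j in seq_len(n)) {
            if ((i - cx)^2 + (j - cy)^2 <= r^2) m[i, j] <- 1L
        }
        ang <- runif(1, 0, 2 * pi)
        rNew <- runif(1, n * 0.08, n * 0.18)
        step <- 0.8 * (r + rNew) / 2
        cx <- min(max(cx + step * cos(ang), n * 0.25), n * 0.75)
        cy <- min(max(cy + step * sin(ang), n * 0.25), n * 0.75)
        r <- rNew
    }
    m
}

# straight reference centerline along an arbitrary direction
straightReference <- function(length = 10, radius = 1, spacing = 0.2,
                              dir = c(1, 0, 0), offset = c(0, 0, 0),
                              label = "straight") {
    dir <- dir / sqrt(sum(dir^2))
    s <- seq(0, length, by = spacing)
    pts <- cbind(sweep(outer(s, dir), 2L, offset, "+"), radius)
    ReferenceCenterline(pts, label = label)
}

# O(n^2) metric recount straight from resampled point sets: an independent
# double-loop implementation of the radius-thresholded nearest-neighbour
# classification and the four measures
bruteMetrics <- function(E, R, refRadii, skipMm = 5, otMinRadius = 0.75) {
    nE <- nrow(E); nR <- nrow(R)
    refArc <- c(0, cumsum(sqrt(rowSums(diff(R)^2))))
    extDist <- numeric(nE); nearestRef <- integer(nE)
    for (i in seq_len(nE)) {
        best <- Inf; bi <- 1L
        for (j in seq_len(nR)) {
            dd <- sqrt(sum((E[i, ] - R[j, ])^2))
            if (dd < best) { best <- dd; bi <- j }
        }
        extDist[i] <- best; nearestRef[i] <- bi
    }
    refDist <- numeric(nR)
    for (j in seq_len(nR)) {
        best <- Inf
        for (i in seq_len(nE)) {
            dd <- sqrt(sum((E[i, ] - R[j, ])^2))
            if (dd < best) best <- dd
        }
        refDist[j] <- best
    }
    tpmL <- extDist <= refRadii[nearestRef] + 1e-12
    tprL <- refDist <= refRadii + 1e-12
    ov <- {
        num <- sum(tpmL) + sum(tprL)
        den <- num + sum(!tpmL) + sum(!tprL)
        if (den == 0) 0 else 100 * num / den
    }
    fnBeyond <- which(!tprL & refArc > skipMm)
    of <- if (length(fnBeyond) == 0L)
        100 * (sum(tprL) + sum(!tprL & refArc <= skipMm)) / nR
    else
        100 * sum(tprL[seq_len(fnBeyond[1L] - 1L)]) / nR
    okR <- which(refRadii >= otMinRadius)
    ot <- if (length(okR) == 0L) NA_real_ else {
        last <- max(okR)
        extIn <- which(nearestRef <= last)
        num <- sum(tpmL[extIn]) + sum(tprL[seq_len(last)])
        den <- length(extIn) + last
        if (den == 0) NA_real_ else 100 * num / den
    }
    dists <- c(extDist[tpmL], refDist[tprL])
    ai <- if (length(dists) == 0L) NA_real_ else mean(dists)
    list(ov = ov, of = of, ot = ot, ai = ai,
         tpm = sum(tpmL), fp = sum(!tpmL), tpr = sum(tprL), fn = sum(!tprL))
}

# uniform resampling oracle used to feed bruteMetrics (plain linear
# interpolation written out directly)
bruteResample <- function(P, n) {
    arc <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
    s <- seq(0, arc[length(arc)], length.out = n)
    out <- matrix(0, n, 3L)
    for (c in 1:3)
        out[, c] <- approx(arc, P[, c], xout = s, ties = "ordered", rule = 2)$y
    out
}
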