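# small capsule volume along a coordinate axis, plus its true-axis voxels
axisCapsule <- function(len = 3, r = 1, dir = c(0, 0, 1)) {
    ref <- straightReference(length = len, radius = r, spacing = 0.2,
                             dir = dir)
    voxelizeSpheres(roundCenterline(ref), voxelSize = 0.1, margin = r)
}

test_that("each per-axis surface of a ball contains the ball center voxel", {
    ref <- roundCenterline(
        ReferenceCenterline(rbind(c(0, 0, 0, 1), c(0.04, 0, 0, 1)), "ball"))
    vol <- voxelizeSpheres(ref, voxelSize = 0.1, margin = 1)
    ctr <- mmToVoxel(c(0, 0, 0), vol)
    for (ax in c("x", "y", "z")) {
        s <- medialSurface(vol, ax)
        v <- voxels(s)
        expect_true(all(volumeGrid(vol)[v + 1L] == 1L))  # surface is interior
        hit <- apply(abs(sweep(v, 2L, ctr)), 1L, max)
        expect_true(any(hit <= 1))
    }
    # empty volume: empty surface
    empty <- BinaryVolume(array(0L, c(5L, 5L, 5L)))
    expect_equal(nrow(voxels(medialSurface(empty, "x"))), 0L)
})

test_that("a z-cylinder's x-surface concentrates on the axis plane", {
    vol <- axisCapsule(dir = c(0, 0, 1))
    axisIdx <- mmToVoxel(c(0, 0, 0), vol)
    sx <- medialSurface(vol, "x")
    v <- voxels(sx)
    # skeletons of the lengthwise strips sit on the mid-plane j = axis j
    expect_true(all(abs(v[, 2L] - axisIdx[2L]) <= 1))
})

test_that("common surfaces intersect, are symmetric and respect tolerance", {
    a <- MedialSurface(rbind(c(1L, 1L, 1L), c(2L, 2L, 2L)), "x")
    b <- MedialSurface(rbind(c(1L, 1L, 1L), c(9L, 9L, 9L)), "y")
    expect_identical(voxels(commonSurface(a, b, 0L)),
                     rbind(c(i = 1L, j = 1L, k = 1L)))
    expect_equal(variantName(commonSurface(a, b, 0L)), "XY")
    far <- MedialSurface(rbind(c(50L, 50L, 50L)), "y")
    expect_equal(nrow(voxels(commonSurface(a, far, 0L))), 0L)
    # identical sets are idempotent at tol 0
    a2 <- MedialSurface(voxels(a), "z")
    expect_identical(voxels(commonSurface(a, a2, 0L)), voxels(a))
    # symmetry
    s1 <- commonSurface(a, b, 1L); s2 <- commonSurface(b, a, 1L)
    k <- function(v) sort(v[, 1L] + v[, 2L] * 1e3 + v[, 3L] * 1e6)
    expect_identical(k(voxels(s1)), k(voxels(s2)))
    expect_error(commonSurface(a, MedialSurface(voxels(b), "x")),
                 "different slicing axes")
    expect_equal(variantName(commonSurface(MedialSurface(voxels(a), "y"),
                                           MedialSurface(voxels(b), "z"), 0L)),
                 "YZ")
})

test_that("the three-way intersection refines the pairwise ones", {
    vol <- axisCapsule(dir = c(0, 0, 1))
    sx <- medialSurface(vol, "x")
    sy <- medialSurface(vol, "y")
    sz <- medialSurface(vol, "z")
    # identical inputs, tol 0: the set itself
    same <- MedialSurface(voxels(sx), "y")
    same2 <- MedialSurface(voxels(sx), "z")
    k <- function(v) sort(v[, 1L] + v[, 2L] * 1e3 + v[, 3L] * 1e6)
    expect_identical(k(voxels(xyzCommon(sx, same, same2, 0L))), k(voxels(sx)))
    # XYZ at tol 0 is contained in every pairwise common at tol 0
    xyz0 <- k(voxels(xyzCommon(sx, sy, sz, 0L)))
    expect_true(all(xyz0 %in% k(voxels(commonSurface(sx, sy, 0L)))))
    expect_true(all(xyz0 %in% k(voxels(commonSurface(sy, sz, 0L)))))
    expect_true(all(xyz0 %in% k(voxels(commonSurface(sx, sz, 0L)))))
    expect_error(xyzCommon(sx, sy, MedialSurface(voxels(sz), "y")),
                 "one surface per slicing axis")
})

test_that("all four variants recover a capsule's axis almost completely", {
    ref <- straightReference(length = 3, radius = 1, spacing = 0.2,
                             dir = c(0, 0, 1))
    vol <- voxelizeSpheres(roundCenterline(ref), voxelSize = 0.1, margin = 1)
    truth <- mmToVoxel(centerlinePoints(
        ReferenceCenterline(cbind(outer(seq(0, 3, by = 0.1), c(0, 0, 1)), 1),
                            "t")), vol)
    sx <- medialSurface(vol, "x")
    sy <- medialSurface(vol, "y")
    sz <- medialSurface(vol, "z")
    sets <- list(XY = commonSurface(sx, sy, 1L),
                 YZ = commonSurface(sy, sz, 1L),
                 XZ = commonSurface(sx, sz, 1L),
                 XYZ = xyzCommon(sx, sy, sz, 1L))
    for (nm in names(sets)) {
        v <- voxels(sets[[nm]])
        expect_true(all(volumeGrid(vol)[v + 1L] == 1L), label = nm)
        covered <- vapply(seq_len(nrow(truth)), function(i)
            any(abs(v[, 1L] - truth[i, 1L]) <= 1 &
                abs(v[, 2L] - truth[i, 2L]) <= 1 &
                abs(v[, 3L] - truth[i, 3L]) <= 1), logical(1L))
        expect_gte(mean(covered), 0.99)
    }
})
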