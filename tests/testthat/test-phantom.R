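test_that("simulated centerlines honour length, spacing and determinism", {
    spec <- phantomSpec("LAD", length = 40, sampleSpacing = 0.4, seed = 5L)
    ref <- simulateCenterline(spec)
    p <- centerlinePoints(ref)
    expect_equal(nrow(p), 101L)
    expect_equal(sum(sqrt(rowSums(diff(p)^2))), 40, tolerance = 0.01)
    expect_identical(simulateCenterline(spec)@points, ref@points)

    # radii interpolate linearly between the endpoints
    expect_equal(radii(ref)[1L], spec@radiusStart)
    expect_equal(radii(ref)[101L], spec@radiusEnd, tolerance = 1e-9)

    # zero tortuosity degenerates to a straight +x segment
    st <- simulateCenterline(phantomSpec("RCA", length = 20, tortuosity = 0,
                                         seed = 1L))
    sp <- centerlinePoints(st)
    expect_true(all(sp[, 2:3] == 0))
    expect_equal(sp[, 1L], seq(0, 20, by = 0.4), tolerance = 1e-9)
})

test_that("tubes that would self-intersect are rejected with the curvature", {
    expect_error(
        simulateCenterline(phantomSpec("RCA", tortuosity = 0.8, seed = 2L)),
        "curvature")
})

test_that("rounding truncates to the grid precision and collapses duplicates", {
    ref <- ReferenceCenterline(rbind(c(1.2345, 0.05, 2.0, 1.2499),
                                     c(5, 5, 5, 1)), "r")
    rr <- roundCenterline(ref)
    expect_equal(unname(rr@points[1L, ]), c(1.2, 0.1, 2.0, 1.2))
    expect_identical(roundCenterline(rr)@points, rr@points)

    # coincident rounded points collapse to one
    ref2 <- ReferenceCenterline(rbind(c(0, 0, 0, 0.5), c(0.04, 0, 0, 0.5)), "d")
    expect_equal(nrow(roundCenterline(ref2)@points), 1L)
})

test_that("union-of-spheres rasterization matches the exhaustive ball test", {
    # single ball
    ref1 <- roundCenterline(
        ReferenceCenterline(rbind(c(0, 0, 0, 0.5), c(0.04, 0, 0, 0.5)), "b"))
    vol1 <- voxelizeSpheres(ref1, voxelSize = 0.1, margin = 0.5)
    expect_identical(volumeGrid(vol1), bruteBallGrid(ref1, vol1))

    # short straight segment, spacing below the radius
    ref2 <- roundCenterline(straightReference(length = 1.2, radius = 0.4,
                                              spacing = 0.3,
                                              dir = c(1, 0.4, 0.2)))
    vol2 <- voxelizeSpheres(ref2, voxelSize = 0.1, margin = 0.4)
    expect_identical(volumeGrid(vol2), bruteBallGrid(ref2, vol2))

    # every foreground voxel of the 2-point capsule satisfies the ball test
    # and lies inside the capsule hull of the two balls
    ref3 <- ReferenceCenterline(rbind(c(0, 0, 0, 0.4), c(0.4, 0, 0, 0.4)), "c")
    vol3 <- voxelizeSpheres(ref3, voxelSize = 0.1, margin = 0.4)
    fg <- which(volumeGrid(vol3) == 1L, arr.ind = TRUE) - 1L
    ctr <- voxelToMm(fg, vol3)
    segd <- apply(ctr, 1L, function(q) {
        t <- min(max(q[1L] / 0.4, 0), 1)
        sqrt(sum((q - c(0.4 * t, 0, 0))^2))
    })
    expect_true(all(segd <= 0.4 + 1e-9))
})

test_that("closed-inequality boundary voxels are included", {
    # voxel center exactly at distance r: 0.5 is exactly representable
    ref <- ReferenceCenterline(rbind(c(0, 0, 0, 0.5), c(0.5, 0, 0, 0.5)), "t")
    vol <- voxelizeSpheres(ref, voxelSize = 0.5, margin = 0.5)
    fg <- voxelToMm(which(volumeGrid(vol) == 1L, arr.ind = TRUE) - 1L, vol)
    expect_true(any(abs(fg[, 1L] - (-0.5)) < 1e-12 & fg[, 2L] == 0 & fg[, 3L] == 0))
})

test_that("enlarging all radii grows the foreground monotonically", {
    ref <- roundCenterline(straightReference(length = 2, radius = 0.4,
                                             spacing = 0.2, dir = c(1, 0.3, 0)))
    volA <- voxelizeSpheres(ref, voxelSize = 0.1, margin = 0.8)
    p2 <- ref@points; p2[, 4L] <- p2[, 4L] + 0.2
    ref2 <- ReferenceCenterline(p2, "bigger")
    volB <- voxelizeSpheres(ref2, voxelSize = 0.1, margin = 0.8)
    # same margin but the box grows with the radii: compare in world space
    fgA <- voxelToMm(which(volumeGrid(volA) == 1L, arr.ind = TRUE) - 1L, volA)
    fgB <- voxelToMm(which(volumeGrid(volB) == 1L, arr.ind = TRUE) - 1L, volB)
    keyA <- paste(round(fgA[, 1L], 6), round(fgA[, 2L], 6), round(fgA[, 3L], 6))
    keyB <- paste(round(fgB[, 1L], 6), round(fgB[, 2L], 6), round(fgB[, 3L], 6))
    expect_true(all(keyA %in% keyB))
})

test_that("ground-truth points lie inside their own tube and budgets are enforced", {
    ref <- roundCenterline(simulateCenterline(phantomSpec("BRANCH", length = 8,
                                                          seed = 3L)))
    vol <- voxelizeSpheres(ref)
    idx <- mmToVoxel(centerlinePoints(ref), vol)
    expect_true(all(volumeGrid(vol)[idx + 1L] == 1L))

    expect_error(voxelizeSpheres(ref, voxelSize = 0.001),
                 "voxel budget")
    expect_error(voxelizeSpheres(ref, margin = 0.1), "margin")
})

test_that("benchmark sets are complete, composed of all classes and reproducible", {
    d1 <- withr::local_tempdir()
    man <- generateBenchmarkSet(1L, d1, seed = 9L, voxelSize = 0.25)
    expect_equal(nrow(man), 4L)
    expect_setequal(sub(".*_(\\w+)\\.txt$", "\\1", man$reference),
                    c("RCA", "LAD", "LCX", "BRANCH"))
    expect_true(all(file.exists(file.path(d1, man$volume))))
    expect_true(file.exists(file.path(d1, "manifest.tsv")))

    d2 <- withr::local_tempdir()
    generateBenchmarkSet(1L, d2, seed = 9L, voxelSize = 0.25)
    for (f in man$reference)
        expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                         readBin(file.path(d2, f), "raw", 1e6))
})
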