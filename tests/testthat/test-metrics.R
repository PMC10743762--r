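refLine <- function(length = 50, radius = 1, n = 26L) {
    s <- seq(0, length, length.out = n)
    ReferenceCenterline(cbind(s, 0, 0, radius), "ref")
}

test_that("a centerline evaluated against itself is perfect", {
    ref <- refLine()
    self <- Centerline(centerlinePoints(ref))
    rep <- evaluateCenterline(self, ref)
    expect_equal(rep@ov, 100)
    expect_equal(rep@of, 100)
    expect_equal(rep@ot, 100)
    expect_equal(rep@ai, 0)
    cnt <- rep@counts$ov
    expect_equal(cnt@tpm, 1000L)
    expect_equal(cnt@tpr, 1000L)
    expect_equal(cnt@fp + cnt@fn, 0L)
})

test_that("an extraction beyond one radius everywhere scores zero overlap", {
    ref <- refLine(radius = 1)
    off <- Centerline(sweep(centerlinePoints(ref), 2L, c(0, 5, 0), "+"))
    rep <- evaluateCenterline(off, ref)
    expect_equal(rep@ov, 0)
    expect_equal(rep@of, 0)
    expect_equal(rep@ot, 0)
    expect_true(is.na(rep@ai))
    # a constant offset inside the radius matches everywhere at that distance
    near <- Centerline(sweep(centerlinePoints(ref), 2L, c(0, 0.5, 0), "+"))
    cls <- classifyPoints(near, ref)
    expect_true(all(cls$extLabels == "TPM"))
    expect_true(all(cls$refLabels == "TPR"))
    expect_equal(cls$extDist, rep(0.5, 1000L), tolerance = 1e-9)
    expect_equal(metricAI(cls), 0.5, tolerance = 1e-9)
})

test_that("an empty extraction turns every reference point into a false negative", {
    ref <- refLine()
    cls <- classifyPoints(NULL, ref)
    expect_equal(cls$counts@fn, 1000L)
    expect_equal(cls$counts@tpm + cls$counts@fp, 0L)
    expect_equal(metricOV(cls), 0)
    expect_equal(metricOF(cls), 0)
})

test_that("overlap ratio follows the count arithmetic", {
    expect_equal(metricOV(MetricCounts(1000L, 0L, 1000L, 0L)), 100)
    expect_equal(metricOV(MetricCounts(0L, 1000L, 0L, 1000L)), 0)
    expect_equal(metricOV(MetricCounts(500L, 500L, 500L, 500L)), 50)
    expect_equal(metricOV(MetricCounts(0L, 0L, 0L, 0L)), 0)
})

test_that("the first five millimetres are forgiven by OF", {
    ref <- refLine(length = 50, radius = 1)
    P <- centerlinePoints(ref)

    # displacement confined to the first 4 mm: no error beyond 5 mm -> 100%
    Pbad <- P; Pbad[P[, 1L] < 4, 2L] <- 3
    rep <- evaluateCenterline(Centerline(Pbad), ref)
    expect_equal(rep@of, 100)
    expect_lt(rep@ov, 100)

    # first failure at 25 mm: OF is the fraction tracked before it
    Pmid <- P; Pmid[P[, 1L] >= 25, 2L] <- 3
    cls <- classifyPoints(Centerline(Pmid), ref)
    firstFN <- which(cls$refLabels == "FN" & cls$refArc > 5)[1L]
    expected <- 100 * sum(cls$refLabels[seq_len(firstFN - 1L)] == "TPR") / 1000
    expect_equal(metricOF(cls), expected)
    expect_equal(metricOF(cls), 50, tolerance = 0.5)
})

test_that("OT restricts the evaluation to the clinically relevant span", {
    # radii taper below 0.75 mm at 80% of the length; errors only distal
    s <- seq(0, 50, length.out = 51L)
    r <- seq(1.5, 0.6, length.out = 51L)        # drops below 0.75 at ~83%
    ref <- ReferenceCenterline(cbind(s, 0, 0, r), "taper")
    P <- centerlinePoints(ref)
    Pbad <- P; Pbad[P[, 1L] > 45, 2L] <- 4      # errors in the distal 10%
    cls <- classifyPoints(Centerline(Pbad), ref)
    expect_equal(metricOT(cls), 100)
    expect_lt(metricOV(cls), 100)

    # no sample reaches the clinical radius: not applicable
    thin <- ReferenceCenterline(cbind(s, 0, 0, 0.5), "thin")
    expect_true(is.na(metricOT(classifyPoints(Centerline(P), thin))))
    expect_true(is.na(evaluateCenterline(Centerline(P), thin)@ot))
})

test_that("AI averages the matched distances of both directions", {
    cls <- list(extLabels = c("TPM", "TPM", "FP"), refLabels = c("TPR", "FN"),
                extDist = c(0.1, 0.3, 9), refDist = c(0.1, 9))
    expect_equal(metricAI(cls), mean(c(0.1, 0.3, 0.1)))
    # equal counts of 0.1 and 0.3 average to 0.2
    cls2 <- list(extLabels = rep("TPM", 4L), refLabels = character(0L),
                 extDist = c(0.1, 0.1, 0.3, 0.3), refDist = numeric(0L))
    expect_equal(metricAI(cls2), 0.2)
})

test_that("all four measures agree with an exhaustive quadratic recount", {
    set.seed(21)
    for (case in 1:3) {
        n <- 40L
        s <- seq(0, 30, length.out = 12L)
        refP <- cbind(s, sin(s / 5), cos(s / 7), 0.5 + 0.1 * case)
        ref <- ReferenceCenterline(refP, "osc")
        ext <- centerlinePoints(ref)
        # perturb a middle stretch beyond the radius, jitter the rest inside
        ext[, 2L] <- ext[, 2L] + 0.2
        if (case > 1) ext[5:7, 3L] <- ext[5:7, 3L] + 2
        cls <- classifyPoints(Centerline(ext), ref, n = n)
        E <- bruteResample(ext, n)
        R <- bruteResample(refP[, 1:3], n)
        refRadii <- approx(c(0, cumsum(sqrt(rowSums(diff(refP[, 1:3])^2)))),
                           refP[, 4L],
                           xout = seq(0, sum(sqrt(rowSums(diff(refP[, 1:3])^2))),
                                      length.out = n), rule = 2)$y
        oracle <- bruteMetrics(E, R, refRadii)
        expect_equal(cls$counts@tpm, oracle$tpm)
        expect_equal(cls$counts@fp, oracle$fp)
        expect_equal(cls$counts@tpr, oracle$tpr)
        expect_equal(cls$counts@fn, oracle$fn)
        expect_equal(metricOV(cls), oracle$ov)
        expect_equal(metricOF(cls), oracle$of)
        expect_equal(metricOT(cls), oracle$ot)
        expect_equal(metricAI(cls), oracle$ai, tolerance = 1e-12)
    }
})

test_that("metrics are invariant to rigid motion and to extracted point order", {
    set.seed(8)
    s <- seq(0, 30, length.out = 20L)
    ref <- ReferenceCenterline(cbind(s, sin(s / 4), 0, 1), "rig")
    ext <- centerlinePoints(ref) + matrix(rnorm(60, 0, 0.2), 20L)
    base <- evaluateCenterline(Centerline(ext), ref, n = 200L)

    # random rotation + translation applied to both curves
    th <- runif(3, 0, 2 * pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
    Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0), c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
    Q <- Rx %*% Rz
    tr <- c(4, -7, 2)
    refT <- ReferenceCenterline(cbind(sweep(centerlinePoints(ref) %*% t(Q), 2L, tr, "+"),
                                      radii(ref)), "rigT")
    extT <- Centerline(sweep(ext %*% t(Q), 2L, tr, "+"))
    moved <- evaluateCenterline(extT, refT, n = 200L)
    expect_equal(metricValues(moved), metricValues(base), tolerance = 1e-6)

    # reversing the extracted point order changes nothing
    rev <- evaluateCenterline(Centerline(ext[20:1, ]), ref, n = 200L)
    expect_equal(metricValues(rev), metricValues(base), tolerance = 1e-9)
})

test_that("AI never exceeds the mean radius over matched reference samples", {
    set.seed(30)
    for (k in 1:5) {
        s <- seq(0, 25, length.out = 15L)
        ref <- ReferenceCenterline(cbind(s, 0, 0, runif(15L, 0.4, 1.5)), "b")
        ext <- centerlinePoints(ref) + matrix(rnorm(45, 0, 0.4), 15L)
        rep <- evaluateCenterline(Centerline(ext), ref, n = 300L)
        if (!is.na(rep@ai))
            expect_lte(rep@ai, rep@counts$meanMatchedRadius + 1e-9)
    }
})
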