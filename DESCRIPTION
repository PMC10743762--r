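Package: VoronoiTrack
Title: Voronoi-Based 3D Centerline Extraction for Tubular Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Divide-and-conquer extraction of 3D centerlines from binary
    tubular segmentations (e.g. segmented coronary arteries). The volume is
    sliced along each coordinate axis, a Voronoi-diagram medial-axis
    approximation is computed for every 2D slice, the per-axis skeleton
    stacks are fused into medial surfaces, and their pairwise and three-way
    intersections yield candidate centerlines that are ordered and
    arc-length resampled. Also provides a union-of-spheres synthetic vessel
    phantom generator (NIfTI output) emulating the four coronary vessel
    classes, and the standardized centerline tracking accuracy metrics
    (overlap OV, overlap until first error OF, overlap of the clinically
    relevant portion OT, and average inside distance AI).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    igraph,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
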