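---
title: "Voronoi-based centerline extraction: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voronoi-based centerline extraction: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind `VoronoiTrack`, the parameters
that matter, the synthetic phantom the package validates itself on, and
the design decisions taken where more than one reasonable implementation
exists. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The extraction model

The input is a binary occupancy volume (1 = vessel lumen) with isotropic
voxels; voxel centers carry world coordinates, `origin` being the mm
position of voxel index (0,0,0), and array axes mapping directly to
world axes. The centerline of a tubular object is approximated in four
stages.

**Per-slice Voronoi skeleton.** The volume is cut into 2D slices
perpendicular to each coordinate axis. Within a slice, each connected
component (8-connectivity) is processed independently, so several vessel
cross-sections in one plane do not interact. The component boundary is
traced as the 0.5 iso-contour of the binary mask (marching squares on
the zero-padded pixel lattice), giving a closed sub-pixel polygon per
boundary loop. Two post-passes condition the contour for use as Voronoi
sites:

* *Smoothing.* A circular moving average over roughly 2 px of contour
  arc. Rationale: the raw marching-squares contour of a pixelated
  near-circular cross-section carries ~0.3 px staircase noise, and the
  Voronoi vertices of a noisy convex arc scatter along the shape's major
  axis far beyond the true medial segment. Smoothing reduces the noise
  below the level at which those bumps generate medial branches while
  staying well inside the package's 0.75 px contour accuracy contract
  (verified in the test suite against an analytic disk).
* *Densification.* Segments are subdivided so consecutive sites are at
  most 1 px apart, making the Voronoi vertex cloud a faithful
  medial-axis approximation.

The Delaunay triangulation of the sites (Bowyer–Watson, compiled code)
yields the Voronoi vertices as triangle circumcenters, each with its
clearance — the circumradius, which by the empty-circle property equals
the distance to the nearest site. A vertex is retained iff

1. its rounded pixel is foreground (rounding is half-away-from-zero,
   the single tie rule used package-wide);
2. its *separation angle* — the widest angle its three defining sites
   subtend at it — is at least 90°. True medial points see at least two
   well-separated boundary contacts (near 180° for a tube lumen);
   spurious vertices produced by near-collinear samples of one flat or
   gently curved boundary arc see a narrow angle. This is the standard
   angle-based criterion of the Voronoi medial-axis literature, and
   without it elongated (obliquely cut) cross-sections keep a tail of
   vertices along their major axis that quadruples the final centerline
   error;
3. it survives *scale-local clearance pruning* at ratio 0.5: the vertex
   is dropped iff some vertex with clearance at least twice its own lies
   within twice that larger clearance. On constant-width components this
   reduces to pruning at half the component's maximum clearance; unlike
   a component-global threshold it does not erase the thin end of a
   tapering cross-section, which would cut visible gaps into the distal
   centerline of a tapering vessel.

Components of three or fewer pixels, or whose vertices all fail the
tests, contribute their pixel centroid — a vessel cap slice is a few
pixels and must still yield a centerline point.

**Medial surfaces and common sets.** Per-slice skeleton points are
snapped to their nearest voxel and unioned across slices into three
medial surfaces (one per slicing axis). Intersecting two surfaces gives
the XY-, YZ- and XZ-common sets; intersecting all three gives
XYZ-common. Because skeletons from different slicing directions are
quantized independently, intersection uses a Chebyshev tolerance,
default 1 voxel (`tolVoxels = 0` is exact set intersection). A voxel of
one surface is kept when each required other surface has a voxel within
the tolerance; the union over source surfaces is returned.

**Ordering and resampling.** The common set is an unordered, roughly
1-voxel-thick point cloud. Points are connected when closer than
`(2·tol + 1)` voxel diagonals, the minimum spanning tree of the largest
connected component is built, and the tree's longest geodesic path
(graph diameter) becomes the centerline — stray voxels and short spurs
drop out naturally. The path is resampled to `n = 1000` uniformly
spaced points by piecewise-linear interpolation in arc length. Linear
rather than spline interpolation: at 0.1 mm quantization the difference
is far below the reported AI precision, and linear interpolation cannot
overshoot. No smoothing is applied by default anywhere in the pipeline
output.

## Accuracy metrics

Both curves are resampled to `n = 1000` points (reference radii
interpolated alongside). An extracted point is a true positive (TPM) if
its nearest reference sample lies within that sample's radius, else a
false positive; a reference sample is a true positive (TPR) if its
nearest extracted point lies within its own radius, else a false
negative. Correspondence is nearest-neighbour in Euclidean distance and
applied symmetrically in both directions — the published metric
definitions state the radius rule for both directions but not the
matching algorithm, so this choice is fixed and documented here.

* `OV = 100 (TPM + TPR) / (TPM + TPR + FP + FN)`; 0/0 reported as 0.
* `OF = 100 · TPR_OF / n`, where `TPR_OF` counts reference true
  positives strictly before the first false negative beyond the first
  5 mm of reference arc length; false negatives within the first 5 mm
  are forgiven (counted as tracked and never the first error), so a
  vessel whose only misses sit at its very origin still scores 100%.
* `OT` recomputes the OV ratio restricted to the reference span up to
  the most distal sample with radius ≥ 0.75 mm (diameter > 1.5 mm) and
  to extracted points whose nearest reference sample lies in that span.
  When no sample reaches the threshold, OT is not applicable (`NA`
  rather than 0, so class averages are not silently deflated).
* `AI` is the mean matched distance pooled over both correspondence
  directions (TPM and TPR); it is bounded above by the mean radius of
  the matched reference samples, and `NA` when nothing matched.

The 5 mm and 0.75 mm thresholds are exposed as `skipMm` and
`otMinRadius`. Matched distances are recomputed from coordinates after
the nearest-neighbour search: the expanded-square distance-matrix form
loses ~8 significant digits to cancellation for near-identical curves,
which would turn an exactly-zero AI into ~5e-8.

## The synthetic phantom

The phantom generator emulates the four vessel classes of the standard
coronary tracking benchmark, whose original data are no longer
downloadable. Each centerline is a smooth curve running along +x with
two low-frequency sinusoidal harmonics in y and z (seeded random
amplitudes and phases, amplitude ≈ `tortuosity × length`), reparametrized
to arc length and truncated at the target length; the radius tapers
linearly. Class presets (chosen once from typical coronary anatomy:
proximal diameters ~3–5 mm for main vessels, distal taper toward ~1.2 mm,
branch vessels shorter and thinner):

| class  | length (mm) | radius start → end (mm) | tortuosity |
|--------|------------|--------------------------|-----------|
| RCA    | 60         | 2.70 → 1.10              | 0.07      |
| LAD    | 50         | 2.00 → 0.80              | 0.06      |
| LCX    | 45         | 1.85 → 0.75              | 0.06      |
| BRANCH | 25         | 1.40 → 0.60              | 0.04      |

Curvature is checked analytically: the local curvature radius must
exceed twice the maximum vessel radius everywhere (otherwise the swept
tube would self-intersect) and violating parameter sets are rejected
with the offending value. Sample spacing defaults to 0.4 mm.

Rasterization follows the union-of-spheres construction: coordinates and
radii are rounded to one decimal (0.1 mm — the voxel size, so rounded
points land exactly on voxel centers of the lattice-anchored grid), and
a voxel is foreground iff its center lies within (closed inequality)
the radius of at least one centerline point. Solid balls are used, not
sphere surface meshes: a hollow shell would change the per-slice
topology (rings instead of disks) and is not what a segmentation of a
vessel lumen looks like. The bounding box covers all spheres plus a
margin (default: the maximum radius) and a 5×10⁸-voxel budget is
enforced before allocation.

Benchmark sets derive per-vessel seeds deterministically from a master
seed (hashing dataset index and vessel class), so the same master seed
reproduces byte-identical reference files. The reference file stores the
*unrounded* simulated centerline while the volume is rasterized from the
rounded copy — mirroring the relationship between annotated ground truth
and a synthetic segmentation built from it.

What the phantom does *not* emulate: bifurcations (the benchmark
evaluates single branches), segmentation noise, intensity artifacts,
anisotropic voxels, and the irregular lumen shapes of diseased vessels.
Passing the phantom benchmark therefore demonstrates the geometric
fidelity of the extraction on clean tubular segmentations; it does not
certify behaviour on imperfect real-world segmentations, where accuracy
is expected to be limited by the segmentation itself.

## Problem sizes and numerical choices

The validation benchmark runs 8 datasets × 4 vessels at 0.1 mm voxels
(volumes up to ~650 × 180 × 180 voxels, ~5 s extraction per vessel per
variant); the oracle-equivalence suites use grids up to 100³ voxels and
slices up to 64², where exhaustive brute-force recomputation is cheap.
Sites are jittered by a deterministic ~1e-4 px pattern before
triangulation to break exact cocircularity (pixelated disks otherwise
produce degenerate Delaunay configurations); the jitter is orders of
magnitude below all stated accuracy bounds and keeps every stage
RNG-free and reproducible. NIfTI spatial header fields are 32-bit
floats, so voxel size and origin are snapped to 7 significant digits on
read, which restores decimal values exactly. Ties in rounding are
always broken half-away-from-zero.

## Known limitations

* Single-branch objects only: the longest-path ordering deliberately
  discards side branches; a bifurcating tree yields its longest limb.
* The intersection tolerance (1 voxel) and the 0.5 prune ratio are
  calibrated for tube-like objects a few to ~60 voxels in radius; very
  thin structures (radius ≈ 1 voxel) degrade toward the centroid
  fallback.
* Volumes must be axis-aligned with positive isotropic scales; the
  reader refuses to reorient rather than guess.
* OF depends on the reference's stated direction (proximal → distal);
  reversing the reference changes which end enjoys the 5 mm forgiveness.
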