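---
title: "Multi-level fiber tractography: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level fiber tractography: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Deterministic FOD-peak tractography follows, at every step, the fiber
orientation least deviating from the current direction. This makes it
reproducible and easy to interpret, but structurally blind to *branching*:
at a bifurcation it commits to one continuation and the other arm of the
bundle is never reconstructed. For bundles such as the corticospinal tract,
whose cortical fanning departs the trunk at high angles, this produces
systematic false negatives — precisely the part of the bundle a
neurosurgical planning workflow most needs.

Multi-level fiber tractography (MLFT) addresses this without giving up
determinism. Tracking records, at every visited point, which FOD peaks of
the containing voxel were available and which one was consumed. Streamlines
that fail to reach a user-defined anatomical target region donate their
*unused* peaks as seeds for a further tracking level; the new level's
branches are tracked from those points along those orientations. After the
final level, every streamline that never reached the target at any level is
discarded. Two rules keep false positives controlled:

* **Crossing-vs-branching discipline.** During propagation, multiple peaks
  in a voxel are treated as crossing fibers (the track passes straight
  through). A peak is promoted to a *branch candidate* only at the next
  level, and only because the pathway it sits on failed to reach the
  target.
* **Target retention.** Branching can generate spurious candidates freely
  (both antipodal signs of every unused peak are launched); anatomy prunes
  them, since a retained pathway must reach the target itself or carry a
  descendant that does.

Level 1 is conventional bidirectional deterministic tracking; level L >= 2
consists of unidirectional branches seeded from level L-1's non-reaching
streamlines. The default is two levels; iteration also stops early when a
level contributes no new target-reaching streamline (the convergence rule
this package adopts, since stopping once branching stops paying is the
natural fixed point of the procedure).

## Pipeline and model components

`makeBranchingPhantom()` -> `estimateResponse()` -> `fitCSD()` ->
`extractPeaks()` -> `runMLFT()` -> `composePathways()` -> metrics.

### Fiber orientation distributions

FODs are estimated by single-shell constrained spherical deconvolution.
The signal, normalized per voxel by its mean b = 0 intensity, is
deconvolved with a single-fiber response estimated from ground-truth
single-fiber voxels (tensor-reoriented to +z, pooled, projected on the
zonal harmonics). The deconvolution solves, per voxel,

    min_f || A f - s ||^2 + lambda^2 || L f ||^2

where `A` is the forward convolution at the gradient directions and `L`
collects the rows of a 300-direction amplitude matrix where the current
FOD falls below a threshold of 0.1 times the mean amplitude of the
initial (order-4, unconstrained) estimate. The active set is iterated to a
fixed point (at most 50 iterations; non-converged voxels are zeroed and
counted). `lambda = 1` is scaled by the Frobenius-norm ratio of the signal
and constraint matrices; we verified on the phantom that peak accuracy is
flat in a wide window around this value, with over-weighting slowly
introducing noiseless bias.

The SH basis is real, even-order (antipodally symmetric by construction),
unit-orthonormal, ordered l = 0, 2, ..., lmax with m = -l..l, where m < 0
pairs with sine and m > 0 with cosine terms. `shIndexTable()` documents the
layout; import of coefficient volumes from other conventions amounts to a
column permutation/sign flip against that table.

### Peak extraction

Candidates are local maxima on a dense antipodally symmetric grid (724
hemisphere representatives, i.e. 1448 directions), refined by a damped
Newton ascent in the local tangent plane with finite-difference
derivatives (h = 1e-5, which keeps truncation error near 1e-8 for lmax 8).
Refined peaks are deduplicated within 15 degrees, thresholded at an FOD
amplitude of 0.1 (absolute, after b = 0 normalization — the common default
of deterministic CSD trackers; a threshold relative to the largest peak
would change behaviour in partial-volume voxels), and truncated to 4 per
voxel. Peaks are fixed points of the refinement: the tests assert a
tangential gradient norm below 1e-6.

### Tracking

First-order Euler steps of half a voxel, 45-degree angle threshold, peaks
of the *containing* voxel (nearest-voxel lookup). These choices are
deliberate: branch harvesting needs a well-defined "available vs used"
record per voxel, which interpolated orientations would blur, and
higher-order integrators would spread each step's bookkeeping over several
sub-evaluations. Ties between equally deviating peaks go to the higher
amplitude, then the lower peak index, keeping runs byte-reproducible.
Seeds are lattice points inside seed voxels (no randomness); each level-1
seed is propagated along both antipodal signs of the voxel's dominant peak
and the halves are merged. Branch propagation is unidirectional — the
backward direction of a branch is its parent's own trajectory. Both
antipodal signs of an unused peak are launched as separate candidates
because the FOD cannot disambiguate sign; the wrong sign dies quickly and
is removed by retention. A branch-seed candidate angularly closer than the
peak-field separation (15 degrees) to the used peak is excluded to avoid
re-tracing the parent. Per-parent (64) and per-level (1e6) seed caps bound
the worst case; the method itself imposes no limit, which is a known
limitation of the approach, and the caps are logged when hit.

## The synthetic phantom

`cstPhantomSpec()` emulates a corticospinal-tract-like configuration:
three bundles joined by two branching spots, imaged with 6 volumes at
b = 0 and 60 electrostatically spread directions at b = 1200 s/mm^2, 1 mm
isotropic, with optional Rician noise (sigma = S0/SNR) at SNR 25 or 15.
Signal is an equal-fraction multi-tensor: one zeppelin (axial 1.7e-3,
radial 0.2e-3 mm^2/s) per fiber population through the voxel and free
water (3.0e-3 mm^2/s) outside the tubes — literature white-matter/CSF
values. Any signal model that creates distinct FOD peaks at the branch
voxels exercises the algorithm; the multi-tensor is the standard choice.

The default geometry is a vertical trunk whose first child departs
mid-trunk at 55 degrees and whose second child departs at the trunk's
distal end at 65 degrees; target ROIs (2.5 mm spheres) sit at the two
branch endpoints, and the seed voxel sits near the trunk's proximal end.
Two properties of this layout are load-bearing rather than cosmetic:

* **Both departures exceed the 45-degree threshold**, so no branch can be
  followed in a single deterministic pass; reaching the targets *requires*
  the second level. The geometry invariants keep each centerline itself
  smooth (tangent continuity well under 15 degrees per mm); the sharp
  angles live between parent and child, which is exactly what
  distinguishes a branch from a bend.
* **The trunk dead-ends at the second branching spot** rather than
  continuing into a target of its own. This is forced by the branching
  rule itself: branch seeds are harvested only from streamlines that reach
  *no* target, and a smooth trunk ending in a target ROI would make every
  level-1 streamline succeed and leave nothing to branch from. A
  trunk-plus-fanning configuration where the trunk itself stops short of
  the cortex is also the anatomically sensible reading of a CST-like
  shape. For the same reason the seed end of the trunk carries the seed
  region rather than a target ROI.

The single seed voxel defaults to one seed point at its centre, matching a
single-seed-point experimental setup; `seedsPerVoxel` accepts the
100-per-voxel style of in vivo seeding.

What the phantom does *not* emulate: gyral folding, axonal dispersion and
bottleneck regions, partial-volume ground truth beyond tube membership,
multi-shell acquisitions, and spatially varying response functions.
Passing the phantom suite therefore demonstrates the algorithmic
properties (branch recovery, retention, determinism, noise behaviour of
the junction reconstruction) — not in vivo accuracy.

## Evaluation metrics

* **TPI** (topography preservation index): pathways are assigned their
  normalized crossing position v in [0, 1] along the longest axis of a
  rectangular ROI (first point inside the box); endpoints are triangulated
  and the TPI is the mean over triangulation edges of |v_j - v_k|. Lower
  is better-organized. The triangulation is a 2D Delaunay of the endpoints
  projected on their best-fit plane — the canonical parameter-free choice;
  collinear degenerate inputs fall back to a path graph along the
  collinear order. The triangulator is a Bowyer-Watson implementation
  tested against a brute-force empty-circumcircle oracle.
* **MADF** (minimum average direct-flip distance): pathways are arc-length
  resampled to 200 points; the distance is the smaller of the direct and
  flipped mean point-to-point distances — symmetric, flip-invariant,
  scale-equivariant, but not a metric (no triangle inequality is claimed).
  `nearestNeighborMADF()` gives the per-pathway minimum over an all-to-all
  matrix.
* **Radial extent**: endpoints are projected into a user-supplied
  90-degree arc (centre plus two bounding rays) and assigned angles from
  the temporo-lateral ray; the extent is max - min of the angles (a
  "coverage" mode summing occupied 5-degree bins is available, since
  either estimator is compatible with how such extents are usually
  reported; range is the default as it produces continuous values).
* **Branch deviation**: against phantom ground truth,
  `branchDirectionDeviation()` scores, per retained streamline and
  branching spot, the mean step direction within 3 mm of the spot against
  the best-matching tangent among the centerlines whose tube (plus half a
  voxel diagonal, reflecting nearest-voxel peak lookup) contains the
  window centroid. Raw streamlines are used rather than composed
  pathways because a composed pathway *turns* from trunk onto branch
  inside the window, and the blend of the two directions is not the
  direction of any reconstructed branch; each streamline traverses the
  window along a single bundle. The step-level variant
  (`branchAngleDeviation()`) is also exported; being a worst case over
  thousands of half-voxel steps, it is dominated by the tail of the
  per-voxel peak-estimation error rather than by the branch geometry.

## Numerical choices and degenerate inputs

* Voxel indices are 0-based and the affine maps voxel *centres* to mm;
  all tracking runs in world mm. The containing voxel is the rounded
  continuous voxel coordinate.
* bvec tables are accepted as 3 x N or N x 3 (auto-detected; the 3 x 3
  ambiguity resolves to the FSL row convention and is logged). Vectors
  with norms within 1e-3 of 1 are re-normalized, anything further off is
  rejected.
* TCK output is Float32LE with NaN separators and an Inf terminator; the
  per-streamline level/parent/target metadata travels in a JSON sidecar
  because neither TCK nor TRK carries arbitrary per-streamline fields
  portably. An empty tractogram writes a valid zero-track file and warns.
* Zero-length pathway segments are dropped before arc-length resampling;
  fully degenerate pathways are errors.
* Empty seed or target regions, seeds outside the volume, geometry
  escaping the phantom grid and broken parent links are hard errors.

## Problem sizes

The phantom suite runs on a 33 x 7 x 32 voxel slab (the bundles live in a
plane, so a thin slab loses nothing), with CSD restricted to the dilated
tube mask (~1100 voxels). One full pipeline realization — phantom, noise,
response, CSD, peaks, two-level MLFT — takes a few seconds; the noise
experiments use 20 fixed-seed realizations per SNR level. These sizes were
chosen so the whole suite, including 40 noisy pipeline realizations,
completes in minutes on a single core while still exercising every stage
at realistic per-voxel dimensions (66 volumes, lmax 8, 45 coefficients).

## Known limitations

* Single-shell CSD only; multi-shell multi-tissue variants are out of
  scope (the phantom has one shell, so they would add nothing here), and
  FOD fields from external tools can be imported instead.
* The branch-count explosion is bounded by caps, not modelled; a
  microstructure-informed level/branch criterion is future work.
* The method is bundle-specific by construction — it needs a seed and a
  target and cannot be combined with whole-brain reconstruction.
* Worst-case branch misalignment at low SNR is governed by the tails of
  the per-voxel peak-estimation error at partial-volume crossing voxels;
  with a 20-realization worst-case statistic, occasional branches
  misaligned by slightly more than 10 degrees at SNR 25 are expected even
  though typical misalignment is a few degrees.
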