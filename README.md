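# mlftrack — multi-level fiber tractography for branching pathways

Deterministic FOD-peak tractography is reproducible and easy to interpret,
but at a fiber bifurcation it follows exactly one continuation: the other
arm of the bundle is never reconstructed. For bundles like the
corticospinal tract, whose cortical fanning leaves the trunk at angles far
above the usual 45° step threshold, this produces systematic false
negatives — a problem for anyone using tractography to delineate a bundle
between two anatomical regions (virtual dissection, presurgical planning).

`mlftrack` implements **multi-level fiber tractography (MLFT)**:
deterministic constrained-spherical-deconvolution (CSD) tracking that
records, at every visited point, which FOD peaks of the containing voxel
were *available* and which one was *used*. Streamlines that fail to reach
a user-defined target region donate their unused peaks as seeds for a
second (third, ...) tracking level; branches are propagated from those
points along those orientations, and finally every pathway that never
reaches the target at any level is discarded. Peaks are treated as
crossings during propagation and become branch candidates only after
their pathway has failed — the rule that separates crossing from
branching. Level 1 therefore *is* conventional deterministic tractography,
and each extra level only adds target-reaching branches.

The package is a complete desk-scale laboratory for the method:

* **Phantom generator** — a CST-like branching phantom (three bundles, two
  branching spots, departures of 55° and 65°), multi-tensor signal with
  6 b=0 + 60 b=1200 s/mm² volumes at 1 mm isotropic, Rician noise at a
  chosen SNR (`cstPhantomSpec()`, `makeBranchingPhantom()`,
  `addRicianNoise()`).
* **FOD estimation** — single-shell CSD with a response estimated from
  single-fiber voxels, even-order real spherical harmonics up to lmax 8,
  soft non-negativity on 300 directions (`estimateResponse()`,
  `fitCSD()`), and Newton-refined peak extraction (`extractPeaks()`).
* **Tracking and MLFT** — Euler propagation at half-voxel steps with
  per-point peak-usage records (`seedStreamlines()`,
  `propagateStreamline()`), branch harvesting, per-level tracking,
  target retention and seed-to-target composition
  (`collectBranchSeeds()`, `runMLFT()`, `composePathways()`).
* **Metrics** — topography preservation index (`tpi()`), minimum average
  direct-flip distance (`madf()`, `nearestNeighborMADF()`), radial extent
  with endpoint density (`radialExtent()`), and branch-direction deviation
  against phantom ground truth (`branchDirectionDeviation()`).
* **I/O** — NIfTI (via RNifti), FSL bval/bvec, MRtrix TCK with a JSON
  sidecar for per-streamline level/parent/target metadata, plus a thin
  command-line front-end at `inst/cli/mlft`
  (`mlft phantom|csd|track|metrics`).

## The statistics at the core

**TPI.** Pathways crossing a rectangular reference ROI are mapped to
v ∈ [0, 1] along its longest axis; their endpoints are Delaunay-
triangulated and every edge (j, k) is weighted w = |v_j − v_k|. The TPI is
the mean weight — 0 when nearby endpoints come from nearby crossings
(topography preserved), larger when the internal order is scrambled.

**MADF.** For two pathways resampled to N = 200 points,
D_AB = min( (1/N) Σ‖a_i − b_i‖, (1/N) Σ‖a_i − b_{N−i+1}‖ ) — the mean
point-to-point distance, invariant to point ordering.

**Radial extent.** Endpoints are projected into a 90° arc (the coronal
projection of the target cortex) and assigned angles from the
temporo-lateral ray; the extent is max − min of the angles.

## Worked example

```r
library(mlftrack)

spec <- cstPhantomSpec(snr = 25, rngSeed = 7)   # noisy CST-like phantom
ph   <- makeBranchingPhantom(spec)
geom <- ph$geometry
affine <- affineMatrix(ph$dwi)
gs     <- dim(signalArray(ph$dwi))[1:3]

resp <- estimateResponse(ph$dwi, singleFiberMask(geom, affine, gs))
fod  <- fitCSD(ph$dwi, resp, mask = tubeMask(geom, affine, gs, dilate = 1L))
pk   <- extractPeaks(fod)                        # threshold 0.1, lmax 8

target <- Reduce(`|`, lapply(geom@endpointROIs, maskArray))
targetMask <- new("RegionMask", mask = target, affine = affine,
                  label = "targets")
tract <- runMLFT(pk, geom@seedMask, targetMask, nLevels = 2L)
tract
#> MultiLevelTractogram: 8 streamlines over 2 levels
#>  level generated retained
#>      1         1        1
#>      2        20        7

branchDirectionDeviation(tract, geom)$maxAngle
#> [1] 4.881835
```

The level-1 pass generates a single trunk streamline that dead-ends at the
distal branching spot without reaching either endpoint ROI (with one level
the retained set is empty — deterministic tracking cannot turn onto the
55°/65° branches). Level 2 launches 20 branch candidates from the unused
peaks recorded along the trunk; the 7 that reach an endpoint ROI are
retained together with their trunk ancestor. The worst misalignment of a
reconstructed branch within 3 mm of a branching spot, here 4.9°, is the
noise-robustness quantity: at SNR 25 branches typically deviate a few
degrees from the ground-truth tangents.

`composePathways(tract)` then yields full seed-to-target polylines
(parent prefix up to the branch point + branch), which is what the TPI,
MADF and extent metrics consume, and
`writeTractogram(tract, "mlft.tck")` exports them with the level/parent
metadata in `mlft.tck.json`.

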