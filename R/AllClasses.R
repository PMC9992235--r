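#' @import methods
#' @importFrom stats rnorm prcomp setNames approx
#' @importFrom graphics hist
#' @importFrom utils head tail
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' Gradient table for a diffusion-weighted acquisition
#'
#' Holds the b-values (s/mm^2) and unit gradient directions of a DWI series,
#' in acquisition order. Directions for b = 0 volumes may be zero vectors;
#' all diffusion-weighted directions must be unit vectors.
#'
#' @slot bvals numeric vector of b-values (s/mm^2), one per volume.
#' @slot bvecs numeric matrix (n x 3) of gradient directions (world frame).
#' @export
setClass("GradientTable",
  representation(bvals = "numeric", bvecs = "matrix"))

setValidity("GradientTable", function(object) {
  msg <- character()
  if (nrow(object@bvecs) != length(object@bvals))
    msg <- c(msg, sprintf("bvec count (%d) does not match bval count (%d)",
                          nrow(object@bvecs), length(object@bvals)))
  if (ncol(object@bvecs) != 3L)
    msg <- c(msg, "bvecs must have 3 columns")
  if (length(object@bvals) && any(object@bvals < 0))
    msg <- c(msg, "b-values must be non-negative")
  dw <- which(object@bvals > 0)
  if (length(dw)) {
    nrm <- sqrt(rowSums(object@bvecs[dw, , drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-6))
      msg <- c(msg, "diffusion-weighted bvecs must be unit vectors (|norm - 1| <= 1e-6)")
  }
  if (length(msg)) msg else TRUE
})

#' 4D diffusion-weighted volume
#'
#' A 4D non-negative signal array (x, y, z, volume) with its voxel-to-world
#' affine and gradient table. Voxel indices are 0-based and the affine maps
#' the centre of voxel (i, j, k) to world mm; all tracking operates in mm.
#'
#' @slot signal 4D numeric array, dimensions (x, y, z, volume).
#' @slot affine 4x4 voxel-index-to-mm matrix (invertible).
#' @slot voxelSize numeric length-3 voxel edge lengths in mm.
#' @slot gradients a \linkS4class{GradientTable}.
#' @export
setClass("DWIVolume",
  representation(signal = "array", affine = "matrix",
                 voxelSize = "numeric", gradients = "GradientTable"))

setValidity("DWIVolume", function(object) {
  msg <- character()
  d <- dim(object@signal)
  if (length(d) != 4L)
    msg <- c(msg, "signal must be a 4D array")
  else if (d[4] != length(object@gradients@bvals))
    msg <- c(msg, sprintf("volume count mismatch: %d gradient entries vs %d volumes",
                          length(object@gradients@bvals), d[4]))
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be 4x4")
  else if (abs(det(object@affine)) < 1e-12)
    msg <- c(msg, "affine is not invertible")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive values")
  if (length(msg)) msg else TRUE
})

#' Binary region-of-interest mask
#'
#' @slot mask logical 3D array on the grid of the volume it annotates.
#' @slot affine 4x4 voxel-index-to-mm matrix.
#' @slot label free-text region name.
#' @export
setClass("RegionMask",
  representation(mask = "array", affine = "matrix", label = "character"))

setValidity("RegionMask", function(object) {
  msg <- character()
  if (length(dim(object@mask)) != 3L) msg <- c(msg, "mask must be 3D")
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (!all(dim(object@affine) == c(4L, 4L))) msg <- c(msg, "affine must be 4x4")
  if (length(msg)) msg else TRUE
})

#' Single-fiber response function
#'
#' Zonal (m = 0, even order) real spherical-harmonic coefficients of the
#' axially symmetric single-fiber signal profile at the working shell,
#' with the fiber aligned to +z. Signal is expressed in units of the mean
#' b = 0 intensity.
#'
#' @slot coeffs numeric vector, one coefficient per even order 0..lmax.
#' @slot lmax even integer, maximum spherical-harmonic order.
#' @slot bvalue numeric, shell b-value (s/mm^2).
#' @export
setClass("ResponseFunction",
  representation(coeffs = "numeric", lmax = "integer", bvalue = "numeric"))

setValidity("ResponseFunction", function(object) {
  msg <- character()
  if (object@lmax %% 2L != 0L || object@lmax < 0L)
    msg <- c(msg, "lmax must be a non-negative even integer")
  if (length(object@coeffs) != object@lmax / 2L + 1L)
    msg <- c(msg, "need one zonal coefficient per even order 0..lmax")
  if (any(!is.finite(object@coeffs))) msg <- c(msg, "coefficients must be finite")
  if (length(msg)) msg else TRUE
})

#' Fiber orientation distribution field
#'
#' Per-voxel even-order real spherical-harmonic coefficients of the FOD.
#' The basis is real, antipodally symmetric and orthonormal; see
#' \code{\link{shBasisMatrix}} for the exact ordering and normalization.
#'
#' @slot coeffs 4D numeric array (x, y, z, nCoeffs).
#' @slot lmax even integer, maximum spherical-harmonic order.
#' @slot affine 4x4 voxel-index-to-mm matrix.
#' @slot mask logical 3D array marking voxels where the fit was performed.
#' @export
setClass("FODField",
  representation(coeffs = "array", lmax = "integer",
                 affine = "matrix", mask = "array"))

setValidity("FODField", function(object) {
  msg <- character()
  d <- dim(object@coeffs)
  if (length(d) != 4L)
    msg <- c(msg, "coeffs must be 4D")
  else if (d[4] != shCoefCount(object@lmax))
    msg <- c(msg, sprintf("coefficient count %d does not match lmax %d (expect %d)",
                          d[4], object@lmax, shCoefCount(object@lmax)))
  if (any(!is.finite(object@coeffs))) msg <- c(msg, "coefficients must be finite")
  if (length(msg)) msg else TRUE
})

#' Per-voxel FOD peak field
#'
#' For every voxel, up to \code{maxPeaks} FOD local maxima sorted by
#' descending amplitude. Peak directions are unit vectors with canonical
#' sign (the FOD is antipodally symmetric, so a peak represents both signs).
#'
#' @slot dirs 5D numeric array (x, y, z, maxPeaks, 3) of unit directions,
#'   NA beyond a voxel's peak count.
#' @slot amps 4D numeric array (x, y, z, maxPeaks) of FOD amplitudes.
#' @slot counts integer 3D array of per-voxel peak counts.
#' @slot affine 4x4 voxel-index-to-mm matrix.
#' @slot threshold numeric, minimum retained FOD amplitude.
#' @slot minSeparation numeric, minimum angular separation (degrees).
#' @export
setClass("PeakField",
  representation(dirs = "array", amps = "array", counts = "array",
                 affine = "matrix", threshold = "numeric",
                 minSeparation = "numeric"))

setValidity("PeakField", function(object) {
  msg <- character()
  dd <- dim(object@dirs)
  if (length(dd) != 5L || dd[5] != 3L) msg <- c(msg, "dirs must be (x,y,z,K,3)")
  if (!identical(dim(object@amps), dd[1:4])) msg <- c(msg, "amps must be (x,y,z,K)")
  if (!identical(dim(object@counts), dd[1:3])) msg <- c(msg, "counts must be (x,y,z)")
  if (object@threshold <= 0) msg <- c(msg, "threshold must be positive")
  if (length(msg)) msg else TRUE
})

#' Deterministic tracking parameters
#'
#' @slot angleThreshold maximum per-step deviation in degrees (0, 90).
#' @slot stepSize Euler step length in mm (default half a voxel).
#' @slot peakThreshold minimum FOD amplitude used for propagation.
#' @slot maxLength maximum streamline length in mm.
#' @slot minLength minimum retained streamline length in mm.
#' @slot stopAtTarget stop propagation once the target region is entered.
#' @export
setClass("TrackingParams",
  representation(angleThreshold = "numeric", stepSize = "numeric",
                 peakThreshold = "numeric", maxLength = "numeric",
                 minLength = "numeric", stopAtTarget = "logical"))

setValidity("TrackingParams", function(object) {
  msg <- character()
  if (object@angleThreshold <= 0 || object@angleThreshold >= 90)
    msg <- c(msg, "angleThreshold must lie strictly between 0 and 90 degrees")
  if (object@stepSize <= 0) msg <- c(msg, "stepSize must be positive")
  if (object@minLength < 0 || object@maxLength <= object@minLength)
    msg <- c(msg, "need maxLength > minLength >= 0")
  if (length(msg)) msg else TRUE
})

#' A streamline with its tracking level and peak-usage record
#'
#' Points are ordered world-mm coordinates. The usage table records, for
#' every visited point, the containing voxel (0-based), how many peaks were
#' available there and which one was consumed. Level 1 streamlines are
#' conventional bidirectional deterministic tracks; level >= 2 streamlines
#' are unidirectional branches with a parent link.
#'
#' @slot points numeric matrix (n x 3), mm.
#' @slot usage data.frame with columns point, i, j, k, nAvailable, used.
#' @slot level integer >= 1.
#' @slot parentId integer id of the parent streamline, or NULL (level 1).
#' @slot branchPointIndex index into the parent's points, or NULL.
#' @slot reachedTarget logical.
#' @slot terminationReason one of angle, amplitude, exited_volume,
#'   entered_target, max_length (forward direction).
#' @slot terminationReasonBackward same enum for the backward half of a
#'   bidirectional level-1 track, NA for branches.
#' @export
setClass("LeveledStreamline",
  representation(points = "matrix", usage = "data.frame", level = "integer",
                 parentId = "integerOrNULL", branchPointIndex = "integerOrNULL",
                 reachedTarget = "logical", terminationReason = "character",
                 terminationReasonBackward = "character"))

.termReasons <- c("angle", "amplitude", "exited_volume", "entered_target",
                  "max_length")

setValidity("LeveledStreamline", function(object) {
  msg <- character()
  if (ncol(object@points) != 3L) msg <- c(msg, "points must be n x 3")
  if (object@level < 1L) msg <- c(msg, "level must be >= 1")
  if (object@level >= 2L && is.null(object@parentId))
    msg <- c(msg, "level >= 2 requires a parent link")
  if (object@level == 1L && !is.null(object@parentId))
    msg <- c(msg, "level 1 streamlines cannot have a parent")
  if (!object@terminationReason %in% .termReasons)
    msg <- c(msg, "unknown termination reason")
  u <- object@usage
  if (nrow(u) && any(!is.na(u$used) & (u$used < 1L | u$used > u$nAvailable)))
    msg <- c(msg, "used peak index outside the available range")
  if (length(msg)) msg else TRUE
})

#' Multi-level tractogram
#'
#' All streamlines retained across MLFT levels, with per-level bookkeeping.
#' After retention, every streamline either reached the target itself or is
#' an ancestor of a branch that did.
#'
#' @slot streamlines list of \linkS4class{LeveledStreamline}, id-indexed.
#' @slot levelsRun integer number of levels executed.
#' @slot counts data.frame with columns level, generated, retained.
#' @slot params the \linkS4class{TrackingParams} used.
#' @export
setClass("MultiLevelTractogram",
  representation(streamlines = "list", levelsRun = "integer",
                 counts = "data.frame", params = "TrackingParams"))

#' Branching-bundle ground-truth geometry
#'
#' Centerlines are dense 3D polylines (mm); each bundle is the set of points
#' within \code{radii} of its centerline (a capsule). Child centerlines start
#' on their parent; \code{branchPoints} lists those departure points.
#'
#' @slot centerlines list of (n x 3) matrices, mm, sampled densely.
#' @slot radii numeric per-bundle tube radius (mm).
#' @slot branchPoints numeric matrix (nBranch x 3), mm.
#' @slot parents integer vector: index of each centerline's parent (NA = root).
#' @slot endpointROIs list of \linkS4class{RegionMask}, one per free terminal
#'   bundle end (target regions).
#' @slot seedMask \linkS4class{RegionMask} for the trunk seed voxel.
#' @export
setClass("BundleGeometry",
  representation(centerlines = "list", radii = "numeric",
                 branchPoints = "matrix", parents = "integer",
                 endpointROIs = "list", seedMask = "RegionMask"))

#' Phantom specification
#'
#' Defines the simulated acquisition: grid, voxel size, gradient scheme
#' (nB0 volumes at b = 0 plus nDWI at bValue), per-compartment diffusivities
#' (mm^2/s), baseline intensity, noise level and RNG seed.
#'
#' @slot geometry a \linkS4class{BundleGeometry}.
#' @slot gridShape integer length-3.
#' @slot voxelSize numeric length-3, mm.
#' @slot nB0,nDWI integer volume counts.
#' @slot bValue numeric, s/mm^2.
#' @slot snr numeric, Inf for noiseless.
#' @slot diffusivities named numeric: axial, radial, iso (mm^2/s).
#' @slot s0 numeric baseline (b = 0) intensity.
#' @slot rngSeed integer seed for the gradient scheme and noise.
#' @export
setClass("PhantomSpec",
  representation(geometry = "BundleGeometry", gridShape = "integer",
                 voxelSize = "numeric", nB0 = "integer", nDWI = "integer",
                 bValue = "numeric", snr = "numeric", diffusivities = "numeric",
                 s0 = "numeric", rngSeed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (!(object@snr > 0)) msg <- c(msg, "snr must be positive (Inf allowed)")
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    msg <- c(msg, "gridShape must be 3 positive integers")
  need <- c("axial", "radial", "iso")
  if (!all(need %in% names(object@diffusivities)))
    msg <- c(msg, "diffusivities must name axial, radial and iso")
  if (length(msg)) msg else TRUE
})
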