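# Generics, accessors and show methods.

#' @rdname accessors
#' @param object an mlftrack S4 object.
#' @export
setGeneric("bValues", function(object) standardGeneric("bValues"))
#' @rdname accessors
#' @export
setGeneric("bVectors", function(object) standardGeneric("bVectors"))
#' @rdname accessors
#' @export
setGeneric("affineMatrix", function(object) standardGeneric("affineMatrix"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("signalArray", function(object) standardGeneric("signalArray"))
#' @rdname accessors
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setGeneric("shCoefficients", function(object) standardGeneric("shCoefficients"))
#' @rdname accessors
#' @export
setGeneric("streamlines", function(object) standardGeneric("streamlines"))
#' @rdname accessors
#' @export
setGeneric("levelCounts", function(object) standardGeneric("levelCounts"))
#' @rdname accessors
#' @export
setGeneric("nPeaks", function(object) standardGeneric("nPeaks"))
#' @rdname accessors
#' @param voxel integer length-3 0-based voxel index.
#' @export
setGeneric("voxelPeaks", function(object, voxel) standardGeneric("voxelPeaks"))

#' Accessors for mlftrack objects
#'
#' Slot access for the core data classes, Bioconductor-style: use these
#' rather than \code{@}.
#'
#' @name accessors
#' @return the corresponding component.
NULL

#' @rdname accessors
#' @export
setMethod("bValues", "GradientTable", function(object) object@bvals)
#' @rdname accessors
#' @export
setMethod("bVectors", "GradientTable", function(object) object@bvecs)
#' @rdname accessors
#' @export
setMethod("bValues", "DWIVolume", function(object) object@gradients@bvals)
#' @rdname accessors
#' @export
setMethod("bVectors", "DWIVolume", function(object) object@gradients@bvecs)
#' @rdname accessors
#' @export
setMethod("affineMatrix", "DWIVolume", function(object) object@affine)
#' @rdname accessors
#' @export
setMethod("affineMatrix", "RegionMask", function(object) object@affine)
#' @rdname accessors
#' @export
setMethod("affineMatrix", "FODField", function(object) object@affine)
#' @rdname accessors
#' @export
setMethod("affineMatrix", "PeakField", function(object) object@affine)
#' @rdname accessors
#' @export
setMethod("voxelSize", "DWIVolume", function(object) object@voxelSize)
#' @rdname accessors
#' @export
setMethod("signalArray", "DWIVolume", function(object) object@signal)
#' @rdname accessors
#' @export
setMethod("maskArray", "RegionMask", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("maskArray", "FODField", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("shCoefficients", "FODField", function(object) object@coeffs)
#' @rdname accessors
#' @export
setMethod("streamlines", "MultiLevelTractogram", function(object) object@streamlines)
#' @rdname accessors
#' @export
setMethod("levelCounts", "MultiLevelTractogram", function(object) object@counts)
#' @rdname accessors
#' @export
setMethod("nPeaks", "PeakField", function(object) object@counts)

#' @rdname accessors
#' @export
setMethod("voxelPeaks", "PeakField", function(object, voxel) {
  stopifnot(length(voxel) == 3L)
  i <- voxel[1] + 1L; j <- voxel[2] + 1L; k <- voxel[3] + 1L
  n <- object@counts[i, j, k]
  if (n == 0L)
    return(list(dirs = matrix(numeric(0), 0, 3), amps = numeric(0)))
  d <- matrix(object@dirs[i, j, k, seq_len(n), ], ncol = 3)
  list(dirs = d, amps = object@amps[i, j, k, seq_len(n)])
})

setMethod("show", "GradientTable", function(object) {
  tab <- table(round(object@bvals))
  cat("GradientTable with", length(object@bvals), "volumes\n")
  cat("  shells (b ~ count):",
      paste(sprintf("%s x %s", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "DWIVolume", function(object) {
  d <- dim(object@signal)
  cat("DWIVolume:", paste(d[1:3], collapse = " x "), "voxels,",
      d[4], "volumes\n")
  cat("  voxel size:", paste(signif(object@voxelSize, 3), collapse = " x "),
      "mm\n")
  show(object@gradients)
})

setMethod("show", "RegionMask", function(object) {
  cat("RegionMask '", object@label, "': ", sum(object@mask), " of ",
      length(object@mask), " voxels\n", sep = "")
})

setMethod("show", "ResponseFunction", function(object) {
  cat("ResponseFunction (b =", object@bvalue, "s/mm^2, lmax =",
      object@lmax, ")\n")
  cat("  zonal coefficients:", paste(signif(object@coeffs, 4), collapse = ", "),
      "\n")
})

setMethod("show", "FODField", function(object) {
  d <- dim(object@coeffs)
  cat("FODField:", paste(d[1:3], collapse = " x "), "voxels, lmax =",
      object@lmax, "(", d[4], "coefficients ),", sum(object@mask),
      "voxels fitted\n")
})

setMethod("show", "PeakField", function(object) {
  cat("PeakField:", paste(dim(object@counts), collapse = " x "),
      "voxels, amplitude threshold", object@threshold, "\n")
  cat("  voxels with peaks:", sum(object@counts > 0),
      "; max peaks per voxel:", max(object@counts), "\n")
})

setMethod("show", "TrackingParams", function(object) {
  cat("TrackingParams: angle <=", object@angleThreshold,
      "deg, step", object@stepSize, "mm, peak threshold",
      object@peakThreshold, "\n")
  cat("  length in [", object@minLength, ",", object@maxLength,
      "] mm; stop at target:", object@stopAtTarget, "\n")
})

setMethod("show", "LeveledStreamline", function(object) {
  cat("LeveledStreamline: level", object@level, ",", nrow(object@points),
      "points, reached target:", object@reachedTarget,
      ", stopped:", object@terminationReason, "\n")
})

setMethod("show", "MultiLevelTractogram", function(object) {
  cat("MultiLevelTractogram:", length(object@streamlines),
      "streamlines over", object@levelsRun, "levels\n")
  if (nrow(object@counts)) print(object@counts, row.names = FALSE)
})

setMethod("show", "BundleGeometry", function(object) {
  cat("BundleGeometry:", length(object@centerlines), "bundles,",
      nrow(object@branchPoints), "branch points,",
      length(object@endpointROIs), "endpoint ROIs\n")
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", paste(object@gridShape, collapse = " x "), "grid,",
      object@nB0, "b0 +", object@nDWI, "volumes at b =", object@bValue,
      ", SNR =", object@snr, "\n")
})
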