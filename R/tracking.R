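# Deterministic FOD-peak streamline tracking.

#' @useDynLib mlftrack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct tracking parameters
#'
#' Defaults follow the standard deterministic setup: 45-degree angle
#' threshold, step of half a voxel (0.5 mm at 1 mm isotropic), FOD peak
#' amplitude threshold 0.1. \code{minLength} defaults to 0, appropriate for
#' phantom-scale data; around 10 mm is typical in vivo.
#'
#' @param angleThreshold maximum per-step deviation, degrees.
#' @param stepSize Euler step, mm.
#' @param peakThreshold minimum FOD amplitude used for propagation.
#' @param maxLength,minLength streamline length bounds, mm.
#' @param stopAtTarget stop once the target region is entered.
#' @return a \linkS4class{TrackingParams}.
#' @export
trackingParams <- function(angleThreshold = 45, stepSize = 0.5,
                           peakThreshold = 0.1, maxLength = 250,
                           minLength = 0, stopAtTarget = TRUE) {
  new("TrackingParams", angleThreshold = angleThreshold, stepSize = stepSize,
      peakThreshold = peakThreshold, maxLength = maxLength,
      minLength = minLength, stopAtTarget = stopAtTarget)
}

#' Select the least-deviating peak
#'
#' For each peak the deviation is the angle between the previous direction
#' and the peak axis, taking the smaller of the two antipodal signs; the
#' peak with minimal deviation is returned with its sign resolved to
#' continue forward, or NULL if every deviation exceeds the threshold (or
#' no peaks are given). Ties are broken by higher amplitude, then lower
#' peak index.
#'
#' @param prevDir unit 3-vector, previous step direction.
#' @param dirs numeric matrix (K x 3) of peak directions.
#' @param amps numeric amplitudes.
#' @param angleThreshold degrees.
#' @return list(index, direction, deviation) or NULL.
#' @export
selectPeak <- function(prevDir, dirs, amps, angleThreshold = 45) {
  if (is.null(dirs) || NROW(dirs) == 0L) return(NULL)
  dirs <- matrix(dirs, ncol = 3)
  dots <- drop(dirs %*% prevDir)
  adot <- abs(dots)
  best <- which(adot > max(adot) - 1e-12)
  if (length(best) > 1L) best <- best[order(-amps[best], best)][1] else best <- best[1]
  dev <- acos(min(1, adot[best])) * 180 / pi
  if (dev > angleThreshold) return(NULL)
  list(index = best, direction = sign(dots[best] + (dots[best] == 0)) * dirs[best, ],
       deviation = dev)
}

.reasonNames <- c("angle", "amplitude", "exited_volume", "entered_target",
                  "max_length")

.targetVector <- function(peaks, targetMask) {
  if (is.null(targetMask)) return(integer(0))
  as.integer(targetMask@mask)
}

.runCore <- function(peaks, seed, initDir, params, targetMask) {
  d <- dim(peaks@counts)
  maxSteps <- max(1L, floor(params@maxLength / params@stepSize))
  .propagateCore(as.numeric(peaks@dirs), as.numeric(peaks@amps),
                 as.integer(peaks@counts), as.integer(d),
                 solve(peaks@affine), as.numeric(seed), as.numeric(initDir),
                 params@stepSize, cos(params@angleThreshold * pi / 180),
                 params@peakThreshold, maxSteps,
                 .targetVector(peaks, targetMask), params@stopAtTarget)
}

.usageFrame <- function(core, offset = 0L) {
  keep <- core$voxel[, 1] >= 0L
  data.frame(point = which(keep) + offset,
             i = core$voxel[keep, 1], j = core$voxel[keep, 2],
             k = core$voxel[keep, 3],
             nAvailable = core$nAvailable[keep],
             used = ifelse(core$used[keep] > 0L, core$used[keep], NA_integer_))
}

#' Propagate a single streamline
#'
#' Unidirectional Euler propagation from a seed point along an initial
#' direction, following at each step the least-deviating FOD peak of the
#' containing voxel. Terminates on angle violation, missing peaks
#' (amplitude), leaving the volume, entering the target (when
#' \code{stopAtTarget}) or reaching \code{maxLength}.
#'
#' @param peaks a \linkS4class{PeakField}.
#' @param seed length-3 world-mm seed point (must lie inside the volume).
#' @param initDir unit initial direction.
#' @param params a \linkS4class{TrackingParams}.
#' @param targetMask optional \linkS4class{RegionMask}.
#' @param level,parentId,branchPointIndex streamline provenance metadata.
#' @return a \linkS4class{LeveledStreamline}.
#' @export
propagateStreamline <- function(peaks, seed, initDir, params = trackingParams(),
                                targetMask = NULL, level = 1L,
                                parentId = NULL, branchPointIndex = NULL) {
  d <- dim(peaks@counts)
  v <- containingVoxel(seed, peaks@affine)
  if (any(v < 0) || any(v >= d))
    stop("seed point lies outside the volume")
  core <- .runCore(peaks, seed, initDir / sqrt(sum(initDir^2)), params,
                   targetMask)
  new("LeveledStreamline", points = core$points, usage = .usageFrame(core),
      level = as.integer(level),
      parentId = if (is.null(parentId)) NULL else as.integer(parentId),
      branchPointIndex = if (is.null(branchPointIndex)) NULL
                         else as.integer(branchPointIndex),
      reachedTarget = core$reached,
      terminationReason = .reasonNames[core$reason],
      terminationReasonBackward = NA_character_)
}

# uniform lattice of n points inside the unit voxel cube centred at 0
.voxelLattice <- function(n) {
  m <- ceiling(n^(1 / 3) - 1e-9)
  g <- (seq_len(m) - 0.5) / m - 0.5
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  if (nrow(pts) > n) {
    idx <- unique(round(seq(1, nrow(pts), length.out = n)))
    k <- 1L
    while (length(idx) < n) {      # fill gaps left by rounding collisions
      if (!(k %in% idx)) idx <- c(idx, k)
      k <- k + 1L
    }
    pts <- pts[sort(idx)[seq_len(n)], , drop = FALSE]
  }
  pts
}

#' Seed and track level-1 streamlines
#'
#' Places \code{seedsPerVoxel} points on a uniform lattice inside every
#' seed voxel (deterministic; no randomness) and propagates each
#' bidirectionally along the two antipodal signs of the voxel's
#' largest-amplitude peak. The two half-tracks are merged into one level-1
#' streamline with usage records re-indexed; seeds in voxels with no peak
#' above threshold are skipped and counted.
#'
#' @param peaks a \linkS4class{PeakField}.
#' @param seedMask a non-empty \linkS4class{RegionMask}.
#' @param seedsPerVoxel points per seed voxel (default 1: the voxel centre).
#' @param params a \linkS4class{TrackingParams}.
#' @param targetMask optional \linkS4class{RegionMask}.
#' @return list of \linkS4class{LeveledStreamline}; attribute
#'   \code{skippedSeeds} counts seeds without a usable peak.
#' @export
seedStreamlines <- function(peaks, seedMask, seedsPerVoxel = 1L,
                            params = trackingParams(), targetMask = NULL) {
  vox <- which(seedMask@mask, arr.ind = TRUE) - 1L
  if (nrow(vox) == 0L) stop("empty seed mask")
  lattice <- .voxelLattice(seedsPerVoxel)
  out <- list()
  skipped <- 0L
  for (r in seq_len(nrow(vox))) {
    pk <- voxelPeaks(peaks, vox[r, ])
    usable <- which(pk$amps >= params@peakThreshold)
    if (!length(usable)) { skipped <- skipped + nrow(lattice); next }
    d0 <- pk$dirs[usable[1], ]           # peaks are amplitude-sorted
    centre <- voxelToWorld(vox[r, ], peaks@affine)
    for (s in seq_len(nrow(lattice))) {
      seed <- drop(centre) + lattice[s, ]
      fwd <- .runCore(peaks, seed, d0, params, targetMask)
      bwd <- .runCore(peaks, seed, -d0, params, targetMask)
      nB <- nrow(bwd$points)
      pts <- rbind(bwd$points[rev(seq_len(nB))[-nB], , drop = FALSE],
                   fwd$points)
      uB <- .usageFrame(bwd)
      uB <- uB[uB$point != 1L, , drop = FALSE]
      uB$point <- nB - uB$point + 1L
      uF <- .usageFrame(fwd, offset = nB - 1L)
      usage <- rbind(uB[order(uB$point), , drop = FALSE], uF)
      sl <- new("LeveledStreamline", points = pts, usage = usage,
                level = 1L, parentId = NULL, branchPointIndex = NULL,
                reachedTarget = fwd$reached || bwd$reached,
                terminationReason = .reasonNames[fwd$reason],
                terminationReasonBackward = .reasonNames[bwd$reason])
      if ((nrow(pts) - 1L) * params@stepSize >= params@minLength)
        out[[length(out) + 1L]] <- sl
    }
  }
  attr(out, "skippedSeeds") <- skipped
  out
}
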