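# Branching-bundle DWI phantom.
#
# Three bundles joined by two branching spots, conceptually mimicking the
# corticospinal tract: a trunk whose distal end is the second branching
# spot, with two child bundles departing at angles well above the 45-degree
# tracking threshold. Each bundle is a capsule (all points within a radius
# of its centerline). Per-voxel signal is an equal-fraction multi-tensor:
# one zeppelin per fiber population through the voxel, free water outside
# the tubes.

.unit <- function(v) v / sqrt(sum(v^2))

# sample a straight segment at ~0.5 mm spacing (including both ends)
.segmentPolyline <- function(from, dir, len, spacing = 0.5) {
  s <- seq(0, len, by = spacing)
  if (tail(s, 1) < len) s <- c(s, len)
  sweep(outer(s, dir), 2, from, "+")
}

#' Tangents of a polyline centerline
#'
#' Central finite differences, normalized; one tangent per point.
#'
#' @param centerline numeric matrix (n x 3).
#' @return numeric matrix (n x 3) of unit tangents.
#' @export
centerlineTangents <- function(centerline) {
  n <- nrow(centerline)
  if (n < 2L) stop("centerline needs at least 2 points")
  d <- rbind(centerline[2, ] - centerline[1, ],
             centerline[seq(3, length.out = max(0, n - 2)), , drop = FALSE] -
               centerline[seq(1, length.out = max(0, n - 2)), , drop = FALSE],
             centerline[n, ] - centerline[n - 1, ])
  d / sqrt(rowSums(d^2))
}

# default CST-like geometry on a given grid
.cstGeometry <- function(affine, gridShape, radius = 2.0, roiRadius = 2.5) {
  trunkFrom <- c(0, 0, -14); trunkTo <- c(0, 0, 6)
  p1 <- c(0, 0, -2)                      # first branching spot (on the trunk)
  p2 <- trunkTo                          # second spot = trunk's distal end
  a2 <- 55 * pi / 180                    # departure angles, degrees from trunk
  a3 <- 65 * pi / 180
  d2 <- c(-sin(a2), 0, cos(a2))
  d3 <- c(sin(a3), 0, cos(a3))
  len2 <- 12; len3 <- 12
  c1 <- .segmentPolyline(trunkFrom, c(0, 0, 1), sqrt(sum((trunkTo - trunkFrom)^2)))
  c2 <- .segmentPolyline(p1, d2, len2)
  c3 <- .segmentPolyline(p2, d3, len3)
  ends <- rbind(tail(c2, 1), tail(c3, 1))

  centers <- .gridCenters(affine, gridShape)
  roi <- function(pt, label) {
    m <- array(sqrt(colSums((t(centers) - pt)^2)) <= roiRadius, dim = gridShape)
    new("RegionMask", mask = m, affine = affine, label = label)
  }
  seedPt <- c(0, 0, -12)
  vox <- drop(containingVoxel(seedPt, affine))
  seedArr <- array(FALSE, dim = gridShape)
  if (all(vox >= 0) && all(vox < gridShape))
    seedArr[vox[1] + 1, vox[2] + 1, vox[3] + 1] <- TRUE
  # an out-of-grid seed leaves the mask empty; makeBranchingPhantom rejects
  # such undersized grids outright

  new("BundleGeometry",
      centerlines = list(trunk = c1, branch1 = c2, branch2 = c3),
      radii = rep(radius, 3),
      branchPoints = rbind(p1, p2),
      parents = c(NA_integer_, 1L, 1L),
      endpointROIs = list(roi(ends[1, ], "target_branch1"),
                          roi(ends[2, ], "target_branch2")),
      seedMask = new("RegionMask", mask = seedArr, affine = affine,
                     label = "seed"))
}

.gridCenters <- function(affine, gridShape) {
  idx <- as.matrix(expand.grid(i = 0:(gridShape[1] - 1),
                               j = 0:(gridShape[2] - 1),
                               k = 0:(gridShape[3] - 1)))
  voxelToWorld(idx, affine)
}

.phantomAffine <- function() {
  a <- diag(4)
  a[1:3, 4] <- c(-16, -3, -17)
  a
}

#' Default CST-like phantom specification
#'
#' A trunk with two cascaded branching spots: the first child departs
#' mid-trunk at 55 degrees, the second at the trunk's distal end at 65
#' degrees — both above the 45-degree tracking threshold, so neither branch
#' can be followed in a single deterministic pass and a second tracking
#' level is required to reach the branch targets. Acquisition: 6 volumes at
#' b = 0 plus 60 at b = 1200 s/mm^2, 1 mm isotropic. Target ROIs sit at the
#' free ends of the two branches; the trunk's proximal end hosts the seed.
#'
#' @param snr signal-to-noise ratio (S0 / sigma); Inf for noiseless.
#' @param rngSeed seed for the Rician noise draws.
#' @param gridShape grid dimensions (default 33 x 7 x 32 voxels).
#' @return a \linkS4class{PhantomSpec}.
#' @export
cstPhantomSpec <- function(snr = Inf, rngSeed = 1L,
                           gridShape = c(33L, 7L, 32L)) {
  affine <- .phantomAffine()
  geom <- .cstGeometry(affine, as.integer(gridShape))
  new("PhantomSpec",
      geometry = geom, gridShape = as.integer(gridShape),
      voxelSize = c(1, 1, 1), nB0 = 6L, nDWI = 60L, bValue = 1200,
      snr = snr,
      diffusivities = c(axial = 1.7e-3, radial = 0.2e-3, iso = 3.0e-3),
      s0 = 100, rngSeed = as.integer(rngSeed))
}

# For every voxel centre, which bundles contain it and the local tangent.
# Returns data.frame(vox = linear 1-based voxel index, bundle, arc, tx, ty, tz,
# distance), one row per (voxel, bundle) membership.
.voxelFiberTable <- function(geometry, affine, gridShape) {
  centers <- .gridCenters(affine, gridShape)
  out <- vector("list", length(geometry@centerlines))
  for (b in seq_along(geometry@centerlines)) {
    cl <- geometry@centerlines[[b]]
    tg <- centerlineTangents(cl)
    d2 <- matrix(Inf, nrow(centers), 1)
    # squared distances voxel-centres x centerline points
    D <- outer(rowSums(centers^2), rep(1, nrow(cl))) -
      2 * centers %*% t(cl) + outer(rep(1, nrow(centers)), rowSums(cl^2))
    nearest <- max.col(-D, ties.method = "first")
    dmin <- sqrt(pmax(0, D[cbind(seq_len(nrow(D)), nearest)]))
    inside <- dmin <= geometry@radii[b]
    if (any(inside)) {
      out[[b]] <- data.frame(vox = which(inside), bundle = b,
                             arc = nearest[inside],
                             tx = tg[nearest[inside], 1],
                             ty = tg[nearest[inside], 2],
                             tz = tg[nearest[inside], 3],
                             distance = dmin[inside])
    }
  }
  do.call(rbind, out)
}

#' Tube membership mask of the phantom bundles
#'
#' @param geometry a \linkS4class{BundleGeometry}.
#' @param affine 4x4 voxel-to-world matrix.
#' @param gridShape integer length-3.
#' @param dilate integer, number of 6-neighbourhood dilation passes.
#' @return a \linkS4class{RegionMask}.
#' @export
tubeMask <- function(geometry, affine, gridShape, dilate = 0L) {
  tab <- .voxelFiberTable(geometry, affine, gridShape)
  m <- array(FALSE, dim = gridShape)
  m[unique(tab$vox)] <- TRUE
  for (pass in seq_len(dilate)) m <- .dilate6(m)
  new("RegionMask", mask = m, affine = affine, label = "tubes")
}

.dilate6 <- function(m) {
  d <- dim(m)
  out <- m
  sh <- function(arr, ax, by) {
    idx <- lapply(d, seq_len)
    src <- idx
    src[[ax]] <- pmin(pmax(idx[[ax]] + by, 1L), d[ax])
    arr[src[[1]], src[[2]], src[[3]]]
  }
  for (ax in 1:3) for (by in c(-1L, 1L)) out <- out | sh(m, ax, by)
  out
}

#' Ground-truth single-fiber mask
#'
#' Voxels whose centre lies inside exactly one tube, away from branching
#' spots; used to estimate the deconvolution response function.
#'
#' @param geometry a \linkS4class{BundleGeometry}.
#' @param affine 4x4 voxel-to-world matrix.
#' @param gridShape integer length-3.
#' @param branchMargin exclusion radius (mm) around branch points.
#' @param coreRadius keep only voxels within this distance of a centerline
#'   (defaults to half the tube radius, avoiding edge partial-volume).
#' @return a \linkS4class{RegionMask}.
#' @export
singleFiberMask <- function(geometry, affine, gridShape, branchMargin = 4,
                            coreRadius = NULL) {
  if (is.null(coreRadius)) coreRadius <- min(geometry@radii) / 2
  tab <- .voxelFiberTable(geometry, affine, gridShape)
  nMember <- table(tab$vox)
  single <- as.integer(names(nMember)[nMember == 1L])
  tab1 <- tab[tab$vox %in% single & tab$distance <= coreRadius, ]
  centers <- .gridCenters(affine, gridShape)
  keep <- rep(TRUE, nrow(tab1))
  for (r in seq_len(nrow(geometry@branchPoints))) {
    bp <- geometry@branchPoints[r, ]
    keep <- keep & sqrt(colSums((t(centers[tab1$vox, , drop = FALSE]) - bp)^2)) > branchMargin
  }
  m <- array(FALSE, dim = gridShape)
  m[tab1$vox[keep]] <- TRUE
  new("RegionMask", mask = m, affine = affine, label = "single_fiber")
}

#' Synthesize the branching phantom
#'
#' Per voxel, the local fiber directions are the tangents of every
#' centerline whose tube contains the voxel centre. The diffusion-weighted
#' signal is an equal-fraction sum of zeppelin tensors oriented along those
#' tangents; voxels outside all tubes carry an isotropic (free-water)
#' compartment. b = 0 volumes equal s0 everywhere. Rician noise is added
#' when the spec's SNR is finite.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list with elements \code{dwi} (a \linkS4class{DWIVolume}) and
#'   \code{geometry} (the ground-truth \linkS4class{BundleGeometry}).
#' @export
makeBranchingPhantom <- function(spec) {
  validObject(spec)
  affine <- spec@geometry@seedMask@affine
  gridShape <- spec@gridShape
  lo <- voxelToWorld(c(0, 0, 0), affine) - spec@voxelSize / 2
  hi <- voxelToWorld(gridShape - 1, affine) + spec@voxelSize / 2
  # geometry must fit in the grid with its tube radius
  allPts <- do.call(rbind, spec@geometry@centerlines)
  rmax <- max(spec@geometry@radii)
  if (any(t(t(allPts) - as.numeric(lo)) < rmax) ||
      any(t(as.numeric(hi) - t(allPts)) < rmax))
    stop("phantom geometry escapes the grid (including tube radius)")

  bvals <- c(rep(0, spec@nB0), rep(spec@bValue, spec@nDWI))
  gdirs <- repulsionDirections(spec@nDWI, seed = 42L)
  bvecs <- rbind(matrix(0, spec@nB0, 3), gdirs)

  nVox <- prod(gridShape)
  nVol <- spec@nB0 + spec@nDWI
  ax <- spec@diffusivities[["axial"]]; rad <- spec@diffusivities[["radial"]]
  iso <- spec@diffusivities[["iso"]]; b <- spec@bValue

  # diffusion-weighted attenuation, all voxels isotropic by default
  att <- matrix(exp(-b * iso), nVox, spec@nDWI)
  tab <- .voxelFiberTable(spec@geometry, affine, gridShape)
  if (nrow(tab)) {
    Tg <- as.matrix(tab[, c("tx", "ty", "tz")])
    dot2 <- (Tg %*% t(gdirs))^2
    contrib <- exp(-b * rad - b * (ax - rad) * dot2)
    summed <- rowsum(contrib, tab$vox)
    voxIds <- as.integer(rownames(summed))
    counts <- tabulate(tab$vox, nbins = nVox)[voxIds]
    att[voxIds, ] <- summed / counts
  }
  sig <- cbind(matrix(1, nVox, spec@nB0), att) * spec@s0
  if (is.finite(spec@snr))
    sig <- addRicianNoise(sig, spec@snr, s0 = spec@s0, rngSeed = spec@rngSeed)
  dim(sig) <- c(gridShape, nVol)

  dwi <- new("DWIVolume", signal = sig, affine = affine,
             voxelSize = spec@voxelSize,
             gradients = new("GradientTable", bvals = bvals, bvecs = bvecs))
  list(dwi = dwi, geometry = spec@geometry)
}

#' Add Rician noise to magnitude MR signal
#'
#' noisy = sqrt((S + n1)^2 + n2^2) with n1, n2 ~ Normal(0, sigma^2) and
#' sigma = s0 / snr. Independent draws per voxel and volume; reproducible
#' for a given seed. An infinite SNR returns the input unchanged.
#'
#' @param signal numeric array of non-negative signal values.
#' @param snr signal-to-noise ratio (s0 / sigma), positive; may be Inf.
#' @param s0 reference intensity defining sigma (mean noiseless b = 0).
#' @param rngSeed integer seed.
#' @return array of the same shape.
#' @export
addRicianNoise <- function(signal, snr, s0, rngSeed = 1L) {
  stopifnot(snr > 0)
  if (is.infinite(snr)) return(signal)
  sigma <- s0 / snr
  set.seed(as.integer(rngSeed))
  n1 <- rnorm(length(signal), sd = sigma)
  n2 <- rnorm(length(signal), sd = sigma)
  out <- sqrt((signal + n1)^2 + n2^2)
  dim(out) <- dim(signal)
  out
}
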