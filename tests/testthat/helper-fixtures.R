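# Shared fixtures, built in code and cached across test files.

.fixtures <- new.env(parent = emptyenv())

# full noiseless phantom pipeline: phantom -> response -> CSD -> peaks ->
# two-level MLFT; reused by the fod, tracking, mlft and acceptance tests
noiselessRun <- function() {
  if (!is.null(.fixtures$noiseless)) return(.fixtures$noiseless)
  spec <- cstPhantomSpec()
  ph <- makeBranchingPhantom(spec)
  geom <- ph$geometry
  affine <- affineMatrix(ph$dwi)
  gs <- dim(signalArray(ph$dwi))[1:3]
  resp <- estimateResponse(ph$dwi, singleFiberMask(geom, affine, gs))
  fod <- fitCSD(ph$dwi, resp, mask = tubeMask(geom, affine, gs, dilate = 1L))
  pk <- extractPeaks(fod)
  target <- targetUnion(geom)
  tr2 <- runMLFT(pk, geom@seedMask, target, nLevels = 2L)
  .fixtures$noiseless <- list(spec = spec, ph = ph, geom = geom,
                              affine = affine, gs = gs, resp = resp,
                              fod = fod, pk = pk, target = target, tr2 = tr2)
  .fixtures$noiseless
}

# union of the phantom's endpoint ROIs as one target region
targetUnion <- function(geom) {
  m <- Reduce(`|`, lapply(geom@endpointROIs, maskArray))
  new("RegionMask", mask = m, affine = geom@seedMask@affine, label = "targets")
}

# one noisy realization of the full pipeline, returning the tractogram and
# ground truth (used by the noise-robustness criterion)
noisyRun <- function(snr, seed) {
  spec <- cstPhantomSpec(snr = snr, rngSeed = seed)
  ph <- makeBranchingPhantom(spec)
  geom <- ph$geometry
  affine <- affineMatrix(ph$dwi)
  gs <- dim(signalArray(ph$dwi))[1:3]
  resp <- estimateResponse(ph$dwi, singleFiberMask(geom, affine, gs))
  fod <- fitCSD(ph$dwi, resp, mask = tubeMask(geom, affine, gs, dilate = 1L))
  pk <- extractPeaks(fod)
  tr <- runMLFT(pk, geom@seedMask, targetUnion(geom), nLevels = 2L)
  list(tr = tr, geom = geom)
}

# uniform synthetic peak field: every voxel holds the same peaks
uniformPeakField <- function(dims, dirs, amps, affine = NULL,
                             threshold = 0.1) {
  dirs <- matrix(dirs, ncol = 3)
  K <- nrow(dirs)
  if (is.null(affine)) {
    affine <- diag(4)
    affine[1:3, 4] <- -(dims - 1) / 2   # centre the grid on the origin
  }
  dd <- array(NA_real_, dim = c(dims, K, 3))
  aa <- array(NA_real_, dim = c(dims, K))
  for (q in seq_len(K)) {
    for (c_ in 1:3) dd[, , , q, c_] <- dirs[q, c_]
    aa[, , , q] <- amps[q]
  }
  new("PeakField", dirs = dd, amps = aa,
      counts = array(K, dim = dims), affine = affine,
      threshold = threshold, minSeparation = 15)
}

# empty region mask on a grid
emptyMask <- function(dims, affine) {
  new("RegionMask", mask = array(FALSE, dim = dims), affine = affine,
      label = "empty")
}

# independent log-linear tensor-fit oracle (kept deliberately separate from
# the package's internal fit): returns FA
oracleFA <- function(signal, bvals, bvecs) {
  g <- bvecs
  X <- cbind(1, -bvals * g[, 1]^2, -bvals * g[, 2]^2, -bvals * g[, 3]^2,
             -2 * bvals * g[, 1] * g[, 2], -2 * bvals * g[, 1] * g[, 3],
             -2 * bvals * g[, 2] * g[, 3])
  b <- solve(crossprod(X), crossprod(X, log(pmax(signal, 1e-12))))
  D <- matrix(c(b[2], b[5], b[6], b[5], b[3], b[7], b[6], b[7], b[4]), 3, 3)
  l <- eigen(D, symmetric = TRUE)$values
  sqrt(1.5 * sum((l - mean(l))^2) / sum(l^2))
}

# angle in degrees between two axes (sign-insensitive)
axisAngle <- function(a, b) {
  acos(min(1, abs(sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
}

# which endpoint ROIs contain at least one composed-pathway endpoint
roisReached <- function(tractogram, geom) {
  paths <- composePathways(tractogram)
  vapply(geom@endpointROIs, function(ro) {
    any(vapply(paths, function(p) {
      v <- containingVoxel(p[nrow(p), ], affineMatrix(ro)) + 1L
      m <- maskArray(ro)
      all(v >= 1L) && all(v <= dim(m)) && m[v[1], v[2], v[3]]
    }, TRUE))
  }, TRUE)
}

# synthetic single-voxel-grid DWI volume from per-voxel multi-tensor
# configurations; dirsList is a list (one entry per voxel along x) of
# matrices of fiber directions (0 rows = isotropic voxel)
syntheticDWI <- function(dirsList, bval = 1200, nB0 = 6, nDWI = 60,
                         ax = 1.7e-3, rad = 0.2e-3, iso = 3.0e-3, s0 = 100) {
  gdirs <- repulsionDirections(nDWI, seed = 42L)
  n <- length(dirsList)
  sig <- array(0, dim = c(n, 1, 1, nB0 + nDWI))
  for (i in seq_len(n)) {
    fd <- dirsList[[i]]
    att <- if (is.null(fd) || nrow(fd) == 0L) {
      rep(exp(-bval * iso), nDWI)
    } else {
      rowMeans(vapply(seq_len(nrow(fd)), function(f) {
        d <- fd[f, ] / sqrt(sum(fd[f, ]^2))
        exp(-bval * rad - bval * (ax - rad) * drop(gdirs %*% d)^2)
      }, numeric(nDWI)))
    }
    sig[i, 1, 1, ] <- c(rep(1, nB0), att) * s0
  }
  new("DWIVolume", signal = sig, affine = diag(4), voxelSize = c(1, 1, 1),
      gradients = new("GradientTable",
                      bvals = c(rep(0, nB0), rep(bval, nDWI)),
                      bvecs = rbind(matrix(0, nB0, 3), gdirs)))
}

# region mask covering every voxel of a grid
fullMask <- function(dims, affine = diag(4)) {
  new("RegionMask", mask = array(TRUE, dim = dims), affine = affine,
      label = "all")
}
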