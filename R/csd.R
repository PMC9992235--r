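# Constrained spherical deconvolution (single shell).
#
# Per voxel, solve min ||A f - s||^2 + lambda^2 ||L f||^2 where A is the
# forward convolution of the FOD with the single-fiber response, and L
# selects the rows of the constraint amplitude matrix B where the current
# FOD amplitude falls below a small threshold (soft non-negativity). The
# active set is iterated until stable.

# rotational-harmonic convolution weights per coefficient: convolving an
# FOD with an axially symmetric kernel multiplies coefficient (l, m) by
# sqrt(4 pi / (2l + 1)) * z_l, z_l the kernel's zonal coefficient.
.convolutionWeights <- function(response, lmax) {
  idx <- shIndexTable(lmax)
  zl <- setNames(response@coeffs, as.character(seq(0, response@lmax, by = 2)))
  w <- sqrt(4 * pi / (2 * idx$l + 1)) * zl[as.character(idx$l)]
  if (any(is.na(w))) stop("response not defined up to lmax = ", lmax)
  as.numeric(w)
}

#' Forward convolution matrix of CSD
#'
#' Maps FOD SH coefficients to predicted shell signal at given directions.
#'
#' @param response a \linkS4class{ResponseFunction}.
#' @param dirs numeric matrix (n x 3) of gradient directions.
#' @param lmax even integer.
#' @return numeric matrix (n x nCoeffs).
#' @export
csdForwardMatrix <- function(response, dirs, lmax) {
  Y <- shBasisMatrix(dirs, lmax)
  sweep(Y, 2, .convolutionWeights(response, lmax), "*")
}

#' Fit fiber orientation distributions by constrained spherical deconvolution
#'
#' Signal is normalized per voxel by its mean b = 0 intensity; the shell
#' signal is deconvolved with the response under a soft non-negativity
#' penalty evaluated on a fixed set of constraint directions. Voxels whose
#' active set has not stabilized after \code{maxIter} iterations are
#' flagged, zeroed and counted.
#'
#' @param dwi a \linkS4class{DWIVolume}.
#' @param response a \linkS4class{ResponseFunction}.
#' @param lmax even integer (default 8).
#' @param mask optional \linkS4class{RegionMask}; voxels outside are skipped.
#' @param shellB shell b-value (defaults to the response's).
#' @param lambda soft-constraint weight (default 1, scaled by the relative
#'   Frobenius norms of the signal and constraint matrices).
#' @param tau amplitude threshold fraction defining the active set
#'   (default 0.1 of the mean initial FOD amplitude).
#' @param maxIter maximum active-set iterations (default 50).
#' @param nConstraint number of constraint directions (default 300).
#' @return a \linkS4class{FODField}; attribute \code{nonConverged} carries
#'   the count of flagged voxels.
#' @export
fitCSD <- function(dwi, response, lmax = 8L, mask = NULL, shellB = NULL,
                   lambda = 1, tau = 0.1, maxIter = 50L, nConstraint = 300L) {
  bvals <- dwi@gradients@bvals
  if (is.null(shellB)) shellB <- response@bvalue
  isB0 <- bvals == 0
  isShell <- abs(bvals - shellB) < 1e-6
  if (!any(isShell)) stop("shell b = ", shellB, " not present in gradients")
  d <- dim(dwi@signal)
  nCoef <- shCoefCount(lmax)
  vox <- if (is.null(mask)) seq_len(prod(d[1:3])) else which(mask@mask)

  sigMat <- matrix(dwi@signal, prod(d[1:3]), d[4])[vox, , drop = FALSE]
  s0 <- rowMeans(sigMat[, isB0, drop = FALSE])
  s0[s0 <= 0] <- 1
  S <- t(sigMat[, isShell, drop = FALSE] / s0)   # nShell x V

  A <- csdForwardMatrix(response, dwi@gradients@bvecs[isShell, , drop = FALSE],
                        lmax)
  B <- shBasisMatrix(hemisphereDirections(2L * nConstraint), lmax)
  lam2 <- (lambda * norm(A, "F") / norm(B, "F"))^2
  AtA <- crossprod(A)
  AtS <- crossprod(A, S)                          # nCoef x V
  BtB <- crossprod(B)

  # initial estimate: unconstrained low-order (lmax 4) fit
  n4 <- shCoefCount(min(lmax, 4L))
  M4 <- AtA[1:n4, 1:n4] + diag(1e-8, n4)
  F0 <- matrix(0, nCoef, ncol(S))
  F0[1:n4, ] <- solve(M4, AtS[1:n4, , drop = FALSE])
  amp0 <- B %*% F0
  thr <- tau * colMeans(amp0)

  out <- matrix(0, nCoef, ncol(S))
  nonConverged <- 0L
  for (v in seq_len(ncol(S))) {
    f <- F0[, v]
    active <- rep(FALSE, nrow(B))
    converged <- FALSE
    for (it in seq_len(maxIter)) {
      newActive <- drop(B %*% f) < thr[v]
      if (it > 1L && identical(newActive, active)) { converged <- TRUE; break }
      active <- newActive
      # BtB minus the inactive rows' contribution avoids a large crossprod
      Bi <- B[!active, , drop = FALSE]
      M <- AtA + lam2 * (BtB - crossprod(Bi))
      f <- solve(M, AtS[, v])
    }
    if (converged) out[, v] <- f else nonConverged <- nonConverged + 1L
  }
  if (nonConverged > 0L)
    message("CSD: ", nonConverged, " voxel(s) did not converge; FOD zeroed")

  coeffs <- array(0, dim = c(d[1:3], nCoef))
  cm <- matrix(coeffs, prod(d[1:3]), nCoef)
  cm[vox, ] <- t(out)
  coeffs <- array(cm, dim = c(d[1:3], nCoef))
  mk <- array(FALSE, dim = d[1:3]); mk[vox] <- TRUE
  fod <- new("FODField", coeffs = coeffs, lmax = as.integer(lmax),
             affine = dwi@affine, mask = mk)
  attr(fod, "nonConverged") <- nonConverged
  fod
}
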