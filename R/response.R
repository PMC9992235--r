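# Single-fiber response estimation: tensor fit for reorientation, signal
# averaging, zonal spherical-harmonic projection.

# Log-linear least-squares diffusion tensor fit.
# signals: V x N matrix, bvals length N, bvecs N x 3. Returns list of
# per-voxel 3x3 tensors, principal eigenvectors and FA.
.fitTensors <- function(signals, bvals, bvecs) {
  g <- bvecs
  X <- cbind(1, -bvals * g[, 1]^2, -bvals * g[, 2]^2, -bvals * g[, 3]^2,
             -2 * bvals * g[, 1] * g[, 2], -2 * bvals * g[, 1] * g[, 3],
             -2 * bvals * g[, 2] * g[, 3])
  Y <- t(log(pmax(signals, 1e-10)))        # N x V
  beta <- qr.solve(X, Y)                   # 7 x V
  V <- ncol(beta)
  e1 <- matrix(0, V, 3); fa <- numeric(V); md <- numeric(V)
  tensors <- vector("list", V)
  for (v in seq_len(V)) {
    b <- beta[, v]
    D <- matrix(c(b[2], b[5], b[6],
                  b[5], b[3], b[7],
                  b[6], b[7], b[4]), 3, 3)
    eg <- eigen(D, symmetric = TRUE)
    l <- eg$values
    e1[v, ] <- eg$vectors[, 1]
    md[v] <- mean(l)
    fa[v] <- sqrt(1.5 * sum((l - md[v])^2) / max(sum(l^2), 1e-20))
    tensors[[v]] <- D
  }
  list(tensors = tensors, e1 = e1, fa = fa, md = md)
}

# rotation taking unit vector v onto +z
.rotationToZ <- function(v) {
  v <- v / sqrt(sum(v^2))
  z <- c(0, 0, 1)
  c_ <- sum(v * z)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  axis <- c(v[2] * z[3] - v[3] * z[2],
            v[3] * z[1] - v[1] * z[3],
            v[1] * z[2] - v[2] * z[1])
  s <- sqrt(sum(axis^2))
  axis <- axis / s
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + s * K + (1 - c_) * (K %*% K)
}

#' Estimate the single-fiber response function
#'
#' For every voxel of the mask, the diffusion tensor's principal
#' eigenvector is estimated and the shell directions are rotated so that
#' it aligns with +z; the b = 0-normalized signals are then pooled over
#' voxels and projected onto the zonal (m = 0) even-order spherical
#' harmonics.
#'
#' @param dwi a \linkS4class{DWIVolume}.
#' @param mask a \linkS4class{RegionMask} of single-fiber voxels.
#' @param lmax even integer (default 8).
#' @param shellB shell b-value; defaults to the largest shell present.
#' @return a \linkS4class{ResponseFunction}.
#' @export
estimateResponse <- function(dwi, mask, lmax = 8L, shellB = NULL) {
  vox <- which(mask@mask)
  if (length(vox) == 0L) stop("empty single-fiber mask")
  if (length(vox) < 5L)
    warning("only ", length(vox), " single-fiber voxels; response may be noisy")
  bvals <- dwi@gradients@bvals
  if (is.null(shellB)) shellB <- max(bvals)
  isB0 <- bvals == 0
  isShell <- abs(bvals - shellB) < 1e-6
  if (!any(isShell)) stop("shell b = ", shellB, " not present")
  d <- dim(dwi@signal)
  sigMat <- matrix(dwi@signal, prod(d[1:3]), d[4])[vox, , drop = FALSE]
  s0 <- rowMeans(sigMat[, isB0, drop = FALSE])
  norm <- sigMat / s0

  fit <- .fitTensors(norm[, isShell | isB0, drop = FALSE],
                     bvals[isShell | isB0],
                     dwi@gradients@bvecs[isShell | isB0, , drop = FALSE])
  gShell <- dwi@gradients@bvecs[isShell, , drop = FALSE]
  rotDirs <- vector("list", length(vox))
  for (v in seq_along(vox))
    rotDirs[[v]] <- gShell %*% t(.rotationToZ(fit$e1[v, ]))
  allDirs <- do.call(rbind, rotDirs)
  allSig <- as.vector(t(norm[, isShell, drop = FALSE]))

  # zonal design: m = 0 columns of the even-order basis
  idx <- shIndexTable(lmax)
  B <- shBasisMatrix(allDirs, lmax)[, idx$m == 0, drop = FALSE]
  z <- qr.solve(B, allSig)
  new("ResponseFunction", coeffs = as.numeric(z), lmax = as.integer(lmax),
      bvalue = shellB)
}

#' Evaluate a response function profile
#'
#' Amplitude of the axially symmetric response at polar angles from the
#' fiber axis (+z).
#'
#' @param response a \linkS4class{ResponseFunction}.
#' @param thetaDeg polar angles in degrees.
#' @return numeric amplitudes.
#' @export
responseProfile <- function(response, thetaDeg) {
  th <- thetaDeg * pi / 180
  dirs <- cbind(sin(th), 0, cos(th))
  idx <- shIndexTable(response@lmax)
  B <- shBasisMatrix(dirs, response@lmax)[, idx$m == 0, drop = FALSE]
  drop(B %*% response@coeffs)
}
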