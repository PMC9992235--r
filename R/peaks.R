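# FOD peak extraction: dense-grid candidates, on-sphere Newton refinement,
# deduplication and thresholding.

# Batched refinement of directions to local maxima of SH-expanded functions.
# C: (M x nCoef) per-row coefficients; U: (M x 3) unit start directions.
# Newton iteration in the local tangent plane, derivatives from a central
# finite-difference stencil (h = 1e-5 keeps truncation ~1e-8 for lmax 8).
# Returns list(dirs, amps, gradNorm, converged).
.refineOnSphere <- function(C, U, lmax, h = 1e-5, tol = 1e-8, maxIter = 15L) {
  M <- nrow(U)
  rot <- function(U, T_, t) {
    ct <- cos(t); st <- sin(t)
    if (length(t) == 1L) { ct <- rep(ct, nrow(U)); st <- rep(st, nrow(U)) }
    U * ct + T_ * st
  }
  amp <- function(D) shEval(C, D, lmax)
  active <- rep(TRUE, M)
  g1 <- g2 <- numeric(M)
  for (it in seq_len(maxIter)) {
    # tangent frame
    ax <- matrix(rep(c(1, 0, 0), each = M), M, 3)
    swap <- abs(U[, 1]) > 0.9
    ax[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), ncol = 3)
    e1 <- cbind(U[, 2] * ax[, 3] - U[, 3] * ax[, 2],
                U[, 3] * ax[, 1] - U[, 1] * ax[, 3],
                U[, 1] * ax[, 2] - U[, 2] * ax[, 1])
    e1 <- e1 / sqrt(rowSums(e1^2))
    e2 <- cbind(U[, 2] * e1[, 3] - U[, 3] * e1[, 2],
                U[, 3] * e1[, 1] - U[, 1] * e1[, 3],
                U[, 1] * e1[, 2] - U[, 2] * e1[, 1])

    A0 <- amp(U)
    A1p <- amp(rot(U, e1, h));  A1m <- amp(rot(U, e1, -h))
    A2p <- amp(rot(U, e2, h));  A2m <- amp(rot(U, e2, -h))
    d12 <- (e1 + e2) / sqrt(2); d1m2 <- (e1 - e2) / sqrt(2)
    hp <- h * sqrt(2)
    App <- amp(rot(U, d12, hp));  Amm <- amp(rot(U, d12, -hp))
    Apm <- amp(rot(U, d1m2, hp)); Amp_ <- amp(rot(U, d1m2, -hp))

    g1 <- (A1p - A1m) / (2 * h); g2 <- (A2p - A2m) / (2 * h)
    H11 <- (A1p - 2 * A0 + A1m) / h^2
    H22 <- (A2p - 2 * A0 + A2m) / h^2
    H12 <- (App + Amm - Apm - Amp_) / (4 * h^2)

    gn <- sqrt(g1^2 + g2^2)
    active <- gn > tol
    if (!any(active)) break

    det <- H11 * H22 - H12^2
    newton <- active & (H11 < 0) & (det > 0)
    s1 <- s2 <- numeric(M)
    s1[newton] <- -( H22[newton] * g1[newton] - H12[newton] * g2[newton]) / det[newton]
    s2[newton] <- -(-H12[newton] * g1[newton] + H11[newton] * g2[newton]) / det[newton]
    asc <- active & !newton
    s1[asc] <- 0.05 * g1[asc] / pmax(gn[asc], 1e-12)
    s2[asc] <- 0.05 * g2[asc] / pmax(gn[asc], 1e-12)
    t <- pmin(sqrt(s1^2 + s2^2), 0.2)
    T_ <- (e1 * s1 + e2 * s2) / pmax(sqrt(s1^2 + s2^2), 1e-300)
    upd <- active & t > 0
    U[upd, ] <- rot(U, T_, t)[upd, , drop = FALSE]
    U <- U / sqrt(rowSums(U^2))
  }
  list(dirs = U, amps = shEval(C, U, lmax),
       gradNorm = sqrt(g1^2 + g2^2), converged = !active)
}

# canonical sign: z > 0, ties broken by y then x
.canonicalSign <- function(D) {
  flip <- D[, 3] < 0 |
    (abs(D[, 3]) < 1e-12 & D[, 2] < 0) |
    (abs(D[, 3]) < 1e-12 & abs(D[, 2]) < 1e-12 & D[, 1] < 0)
  D[flip, ] <- -D[flip, , drop = FALSE]
  D
}

.peakGridEnv <- new.env(parent = emptyenv())

# candidate grid + neighbour table (cached): hemisphere representatives of an
# antipodally symmetric set, with each representative's k nearest neighbours
# measured over the full (both signs) set and mapped back to representatives.
.peakGrid <- function(nMin = 1448, k = 8L) {
  key <- paste0("g", nMin, "_", k)
  if (!is.null(.peakGridEnv[[key]])) return(.peakGridEnv[[key]])
  S <- hemisphereDirections(nMin)
  m <- nrow(S)
  F_ <- rbind(S, -S)
  dots <- S %*% t(F_)
  dots[cbind(seq_len(m), seq_len(m))] <- -Inf      # self
  dots[cbind(seq_len(m), m + seq_len(m))] <- -Inf  # own antipode
  NB <- t(apply(dots, 1, function(r) order(r, decreasing = TRUE)[seq_len(k)]))
  NB <- ifelse(NB > m, NB - m, NB)      # map antipodes to representatives
  out <- list(S = S, NB = NB)
  .peakGridEnv[[key]] <- out
  out
}

#' Extract FOD peaks
#'
#' Candidate maxima are found on a dense antipodally symmetric direction
#' set (>= 724 directions), refined by Newton ascent on the SH amplitude,
#' deduplicated within \code{minSeparation}, thresholded and truncated to
#' \code{maxPeaks} by descending amplitude.
#'
#' @param fod a \linkS4class{FODField}.
#' @param threshold minimum FOD amplitude (absolute, after b = 0
#'   normalization of the signal; default 0.1).
#' @param maxPeaks maximum peaks per voxel (default 4).
#' @param minSeparation minimum angular separation in degrees (default 15).
#' @return a \linkS4class{PeakField}.
#' @export
extractPeaks <- function(fod, threshold = 0.1, maxPeaks = 4L,
                         minSeparation = 15) {
  stopifnot(threshold > 0)
  grid <- .peakGrid()
  S <- grid$S; NB <- grid$NB
  d <- dim(fod@coeffs)
  vox <- which(fod@mask)
  K <- as.integer(maxPeaks)
  nVox <- prod(d[1:3])
  dirsArr <- array(NA_real_, dim = c(nVox, K, 3))
  ampsArr <- array(NA_real_, dim = c(nVox, K))
  counts <- array(0L, dim = d[1:3])
  finish <- function() {
    new("PeakField", dirs = array(dirsArr, dim = c(d[1:3], K, 3)),
        amps = array(ampsArr, dim = c(d[1:3], K)), counts = counts,
        affine = fod@affine, threshold = threshold,
        minSeparation = minSeparation)
  }
  if (!length(vox)) return(finish())

  C <- matrix(fod@coeffs, nVox, d[4])[vox, , drop = FALSE]
  AMP <- C %*% t(shBasisMatrix(S, fod@lmax))     # V x m
  nbMax <- AMP[, NB[, 1]]
  for (j in 2:ncol(NB)) nbMax <- pmax(nbMax, AMP[, NB[, j]])
  cand <- which(AMP >= nbMax & AMP >= 0.7 * threshold, arr.ind = TRUE)
  if (!nrow(cand)) return(finish())

  ref <- .refineOnSphere(C[cand[, 1], , drop = FALSE],
                         S[cand[, 2], , drop = FALSE], fod@lmax)
  D <- .canonicalSign(ref$dirs)
  ok <- ref$amps >= threshold & ref$converged
  cosSep <- cos(minSeparation * pi / 180)

  byVox <- split(which(ok), cand[ok, 1])
  for (nm in names(byVox)) {
    rows <- byVox[[nm]]
    ordr <- rows[order(ref$amps[rows], decreasing = TRUE)]
    keptD <- matrix(0, 0, 3); keptA <- numeric(0)
    for (r in ordr) {
      dr <- D[r, ]
      if (nrow(keptD) && any(abs(keptD %*% dr) > cosSep)) next
      keptD <- rbind(keptD, dr); keptA <- c(keptA, ref$amps[r])
      if (nrow(keptD) >= K) break
    }
    v <- vox[as.integer(nm)]
    n <- nrow(keptD)
    counts[v] <- n
    dirsArr[v, seq_len(n), ] <- keptD
    ampsArr[v, seq_len(n)] <- keptA
  }
  finish()
}
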