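# Real even-order spherical-harmonic basis.
#
# Ordering: orders l = 0, 2, ..., lmax; within each order m = -l..l.
# m < 0 pairs with sin(|m| phi), m > 0 with cos(m phi), m = 0 is zonal.
# Normalization is unit-orthonormal over the sphere, with the
# Condon-Shortley phase carried by the associated Legendre recurrence.
# Only even orders appear, so every basis function (and hence every FOD)
# is antipodally symmetric by construction.

#' Number of even-order SH coefficients up to lmax
#' @param lmax even non-negative integer.
#' @return integer, (lmax + 1)(lmax + 2) / 2.
#' @export
shCoefCount <- function(lmax) {
  stopifnot(lmax >= 0, lmax %% 2 == 0)
  as.integer((lmax + 1) * (lmax + 2) / 2)
}

#' Index table of the even-order real SH basis
#' @param lmax even non-negative integer.
#' @return data.frame with columns l and m in basis order.
#' @export
shIndexTable <- function(lmax) {
  l <- unlist(lapply(seq(0, lmax, by = 2), function(ll) rep(ll, 2 * ll + 1)))
  m <- unlist(lapply(seq(0, lmax, by = 2), function(ll) seq(-ll, ll)))
  data.frame(l = as.integer(l), m = as.integer(m))
}

# Associated Legendre P_l^m(x) for all 0 <= m <= l <= lmax, vectorized over x.
# Returns a list indexed [[l + 1]][[m + 1]] of numeric vectors. Standard
# recurrences with the Condon-Shortley phase.
.legendreAll <- function(lmax, x) {
  s <- sqrt(pmax(0, 1 - x^2))
  P <- vector("list", lmax + 1)
  for (l in 0:lmax) P[[l + 1]] <- vector("list", l + 1)
  P[[1]][[1]] <- rep(1, length(x))
  if (lmax >= 1) {
    for (m in 1:lmax)  # P_m^m = (-1)^m (2m-1)!! (1-x^2)^(m/2)
      P[[m + 1]][[m + 1]] <- (-1)^m * prod(seq(1, 2 * m - 1, by = 2)) * s^m
    for (m in 0:(lmax - 1))  # P_{m+1}^m = x (2m+1) P_m^m
      P[[m + 2]][[m + 1]] <- x * (2 * m + 1) * P[[m + 1]][[m + 1]]
    if (lmax >= 2) {
      for (l in 2:lmax) {
        mtop <- l - 2
        if (mtop >= 0) for (m in 0:mtop)
          P[[l + 1]][[m + 1]] <- (x * (2 * l - 1) * P[[l]][[m + 1]] -
                                  (l + m - 1) * P[[l - 1]][[m + 1]]) / (l - m)
      }
    }
  }
  P
}

# log((l - m)! / (l + m)!) without overflow
.shNorm <- function(l, m) {
  sqrt((2 * l + 1) / (4 * pi) * exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
}

#' Evaluate the real even-order SH basis at a set of directions
#'
#' @param dirs numeric matrix (n x 3) of unit directions.
#' @param lmax even non-negative integer.
#' @return numeric matrix (n x nCoeffs); column order per
#'   \code{\link{shIndexTable}}.
#' @export
shBasisMatrix <- function(dirs, lmax) {
  dirs <- matrix(dirs, ncol = 3)
  z <- pmin(1, pmax(-1, dirs[, 3]))
  phi <- atan2(dirs[, 2], dirs[, 1])
  P <- .legendreAll(lmax, z)
  idx <- shIndexTable(lmax)
  out <- matrix(0, nrow(dirs), nrow(idx))
  for (j in seq_len(nrow(idx))) {
    l <- idx$l[j]; m <- idx$m[j]; am <- abs(m)
    base <- .shNorm(l, am) * P[[l + 1]][[am + 1]]
    out[, j] <- if (m == 0) base
                else if (m > 0) sqrt(2) * base * cos(m * phi)
                else sqrt(2) * base * sin(am * phi)
  }
  out
}

#' Evaluate an SH-expanded function at directions
#'
#' Computes sum_j coeffs_j Y_j(direction) for each direction.
#'
#' @param coeffs numeric coefficient vector (length nCoeffs) or matrix
#'   (n x nCoeffs) with one coefficient row per direction row.
#' @param dirs numeric matrix (n x 3) of unit directions (or length-3 vector).
#' @param lmax even integer; inferred from the coefficient count if missing.
#' @return numeric vector of amplitudes.
#' @export
shEval <- function(coeffs, dirs, lmax = NULL) {
  dirs <- matrix(dirs, ncol = 3)
  if (is.null(dim(coeffs))) {
    if (is.null(lmax)) lmax <- .lmaxFromCount(length(coeffs))
    drop(shBasisMatrix(dirs, lmax) %*% coeffs)
  } else {
    if (is.null(lmax)) lmax <- .lmaxFromCount(ncol(coeffs))
    stopifnot(nrow(coeffs) == nrow(dirs))
    rowSums(coeffs * shBasisMatrix(dirs, lmax))
  }
}

.lmaxFromCount <- function(n) {
  lmax <- (-3 + sqrt(1 + 8 * n)) / 2
  if (abs(lmax - round(lmax)) > 1e-9 || round(lmax) %% 2 != 0)
    stop("coefficient count ", n, " does not match an even-order basis")
  as.integer(round(lmax))
}

#' Project samples onto the even-order SH basis by least squares
#'
#' @param values numeric vector of function samples.
#' @param dirs matrix (n x 3) of unit sample directions.
#' @param lmax even integer.
#' @return numeric coefficient vector.
#' @export
shFit <- function(values, dirs, lmax) {
  B <- shBasisMatrix(dirs, lmax)
  qr.solve(B, values)
}
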