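# Direction sets on the sphere.

#' Fibonacci-spiral point set on the unit sphere
#'
#' Deterministic, approximately uniform set of n points.
#'
#' @param n number of points.
#' @return numeric matrix (n x 3).
#' @export
fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (seq_len(n) - 1)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Dense antipodally symmetric direction set
#'
#' Hemisphere representatives of an antipodally symmetric set with at least
#' \code{nMin} total directions (each representative stands for both signs).
#' Used as the candidate grid for FOD peak finding.
#'
#' @param nMin minimum total direction count (default 1448, i.e. >= 724
#'   hemisphere representatives).
#' @return numeric matrix (m x 3) with m >= nMin / 2, all z >= 0.
#' @export
hemisphereDirections <- function(nMin = 1448) {
  m <- ceiling(nMin / 2)
  pts <- fibonacciSphere(2 * m)
  # the spiral covers z in (-1, 1) uniformly; its upper half is a near-uniform
  # hemisphere sample, and each point represents its antipode as well
  pts[pts[, 3] >= 0, , drop = FALSE][seq_len(m), , drop = FALSE]
}

#' Electrostatic-repulsion gradient scheme
#'
#' Generates n unit gradient directions by minimizing the antipodal Coulomb
#' energy, starting from a seeded jittered Fibonacci hemisphere. The scheme
#' is deterministic given the seed.
#'
#' @param n number of directions.
#' @param seed RNG seed.
#' @param iterations gradient-descent iterations.
#' @return numeric matrix (n x 3) of unit vectors.
#' @export
repulsionDirections <- function(n, seed = 42L, iterations = 200L) {
  set.seed(seed)
  d <- fibonacciSphere(2 * n)
  d <- d[d[, 3] >= 0, , drop = FALSE][seq_len(n), , drop = FALSE]
  d <- d + matrix(rnorm(3 * n, sd = 0.02), n, 3)
  d <- d / sqrt(rowSums(d^2))
  step <- 0.02
  for (it in seq_len(iterations)) {
    G <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      diffm <- sweep(-d, 2, d[i, ], "+")   # d_i - d_j
      summ <- sweep(d, 2, d[i, ], "+")     # d_i + d_j
      r1 <- rowSums(diffm^2); r2 <- rowSums(summ^2)
      r1[i] <- Inf
      G[i, ] <- colSums(diffm / (r1^1.5 + 1e-12)) +
        colSums(summ / (r2^1.5 + 1e-12))
    }
    # project onto tangent plane and take a normalized step
    G <- G - d * rowSums(G * d)
    nrm <- sqrt(rowSums(G^2)); nrm[nrm < 1e-12] <- 1
    d <- d + step * G / nrm
    d <- d / sqrt(rowSums(d^2))
    if (it %% 50 == 0) step <- step / 2
  }
  flip <- d[, 3] < 0
  d[flip, ] <- -d[flip, , drop = FALSE]
  d
}

# minimal angle (degrees) between two unit vectors, sign-insensitive
.angleDeg <- function(a, b) {
  acos(pmin(1, abs(sum(a * b)))) * 180 / pi
}

# pairwise sign-insensitive angles (degrees) between rows of two matrices
.angleDegMat <- function(A, B) {
  acos(pmin(1, abs(A %*% t(B)))) * 180 / pi
}
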