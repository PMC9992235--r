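# Evaluation metrics: topography preservation index (TPI), minimum average
# direct-flip distance (MADF), radial extent with endpoint density, and
# branch-direction deviation against phantom ground truth.

#' Rectangular projection ROI
#'
#' A box given by its centre, orthonormal axes and extents; pathway
#' crossing positions are mapped onto [0, 1] along the longest axis.
#'
#' @param center length-3 centre (mm).
#' @param axes 3x3 matrix with orthonormal axis columns.
#' @param extents length-3 positive box edge lengths (mm).
#' @return list of class \code{ProjectionROI}.
#' @export
projectionROI <- function(center, axes, extents) {
  axes <- as.matrix(axes)
  if (max(abs(crossprod(axes) - diag(3))) > 1e-6)
    stop("axes must be orthonormal columns")
  if (any(extents <= 0)) stop("extents must be positive")
  structure(list(center = as.numeric(center), axes = axes,
                 extents = as.numeric(extents),
                 longestAxis = axes[, which.max(extents)]),
            class = "ProjectionROI")
}

# 0-1 position along the ROI's longest axis of the first pathway point
# inside the box; NA if the pathway misses the box
.roiCrossing <- function(points, roi) {
  q <- sweep(points, 2, roi$center) %*% roi$axes   # n x 3 local coords
  half <- roi$extents / 2
  inside <- abs(q[, 1]) <= half[1] & abs(q[, 2]) <= half[2] &
    abs(q[, 3]) <= half[3]
  if (!any(inside)) return(NA_real_)
  la <- which.max(roi$extents)
  (q[which(inside)[1], la] + half[la]) / roi$extents[la]
}

#' Topography preservation index
#'
#' Each pathway is assigned its normalized crossing position v in [0, 1]
#' along the ROI's longest axis (first point inside the box). Endpoints are
#' triangulated (2D Delaunay on their best-fit plane); every edge (j, k)
#' gets weight |v_j - v_k| and the TPI is the mean weight. Lower values
#' mean better-preserved topographic organization.
#'
#' @param pathways list of (n x 3) point matrices (mm).
#' @param roi a \code{\link{projectionROI}}.
#' @param endpoints optional matrix (n x 3) of per-pathway terminal points;
#'   defaults to each pathway's last point.
#' @return list with \code{v}, \code{edges}, \code{weights}, \code{tpi}
#'   and \code{degenerate} (TRUE when the triangulation fell back to a
#'   collinear path graph).
#' @export
tpi <- function(pathways, roi, endpoints = NULL) {
  if (is.null(endpoints))
    endpoints <- do.call(rbind, lapply(pathways, function(p) p[nrow(p), ]))
  endpoints <- as.matrix(endpoints)
  v <- vapply(pathways, .roiCrossing, numeric(1), roi = roi)
  miss <- is.na(v)
  if (any(miss)) {
    warning(sum(miss), " pathway(s) do not intersect the ROI; excluded")
    v <- v[!miss]; endpoints <- endpoints[!miss, , drop = FALSE]
  }
  if (length(v) < 3L) stop("TPI needs at least 3 ROI-crossing pathways")
  # triangulate endpoints on their best-fit plane
  ctr <- colMeans(endpoints)
  pc <- prcomp(endpoints, center = TRUE)
  xy <- sweep(endpoints, 2, ctr) %*% pc$rotation[, 1:2, drop = FALSE]
  tri <- delaunay2D(xy)
  w <- abs(v[tri$edges[, 1]] - v[tri$edges[, 2]])
  list(v = v, edges = tri$edges, weights = w, tpi = mean(w),
       degenerate = tri$degenerate)
}

#' Resample a polyline uniformly by arc length
#'
#' @param points numeric matrix (n x 3), n >= 2.
#' @param n number of output points.
#' @return numeric matrix (n x 3).
#' @export
resamplePolyline <- function(points, n = 200L) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("polyline needs at least 2 points")
  keep <- c(TRUE, rowSums((points[-1, , drop = FALSE] -
                             points[-nrow(points), , drop = FALSE])^2) > 1e-24)
  points <- points[keep, , drop = FALSE]
  if (nrow(points) < 2L) stop("degenerate zero-length pathway")
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  si <- seq(0, s[length(s)], length.out = n)
  cbind(approx(s, points[, 1], si)$y,
        approx(s, points[, 2], si)$y,
        approx(s, points[, 3], si)$y)
}

#' Minimum average direct-flip distance between two pathways
#'
#' Both pathways are uniformly resampled to \code{nResample} points; the
#' distance is the smaller of the mean point-to-point distance in direct
#' and in flipped order, making it invariant to point ordering.
#'
#' @param a,b numeric matrices (n x 3), mm.
#' @param nResample resampling count (default 200).
#' @return distance in mm.
#' @export
madf <- function(a, b, nResample = 200L) {
  A <- resamplePolyline(a, nResample)
  B <- resamplePolyline(b, nResample)
  direct <- mean(sqrt(rowSums((A - B)^2)))
  flipped <- mean(sqrt(rowSums((A - B[rev(seq_len(nResample)), ])^2)))
  min(direct, flipped)
}

#' Nearest-neighbour MADF distances of a pathway set
#'
#' Computes the all-to-all MADF matrix and, per pathway, the minimum
#' distance to any other pathway.
#'
#' @param pathways list of (n x 3) matrices (>= 2 pathways), or a
#'   \linkS4class{MultiLevelTractogram} (composed pathways are used).
#' @param nResample resampling count.
#' @return list with \code{minima}, \code{distances} (symmetric matrix)
#'   and \code{histogram} (counts over \code{breaks}).
#' @export
nearestNeighborMADF <- function(pathways, nResample = 200L) {
  if (is(pathways, "MultiLevelTractogram"))
    pathways <- composePathways(pathways)
  n <- length(pathways)
  if (n < 2L) stop("need at least 2 pathways")
  R <- lapply(pathways, resamplePolyline, n = nResample)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    direct <- mean(sqrt(rowSums((R[[i]] - R[[j]])^2)))
    flipped <- mean(sqrt(rowSums((R[[i]] -
                                    R[[j]][rev(seq_len(nResample)), ])^2)))
    D[i, j] <- D[j, i] <- min(direct, flipped)
  }
  minima <- vapply(seq_len(n), function(i) min(D[i, -i]), numeric(1))
  list(minima = minima, distances = D,
       histogram = hist(minima, plot = FALSE))
}

#' Define a 90-degree arc segment
#'
#' The arc models the coronal projection of a target region: endpoints are
#' projected onto the plane spanned by the two bounding rays and assigned
#' an angular coordinate from \code{ray0} (0 degrees, temporo-lateral end)
#' towards \code{ray90} (90 degrees).
#'
#' @param center length-3 arc centre (mm).
#' @param ray0 direction of the 0-degree bounding ray.
#' @param ray90 direction of the 90-degree bounding ray.
#' @return list of class \code{ArcSegment}.
#' @export
arcSegment <- function(center, ray0, ray90) {
  e0 <- ray0 / sqrt(sum(ray0^2))
  r9 <- ray90 - sum(ray90 * e0) * e0
  if (sqrt(sum(r9^2)) < 1e-9) stop("bounding rays must not be collinear")
  structure(list(center = as.numeric(center), e0 = e0,
                 e90 = r9 / sqrt(sum(r9^2))),
            class = "ArcSegment")
}

#' Radial extent and angular density of endpoints within a 90-degree arc
#'
#' Each endpoint is projected onto the arc plane and assigned an angle from
#' the 0-degree ray, clamped to [0, 90]. The radial extent is
#' max(angle) - min(angle); the density is a binned angular histogram.
#'
#' @param endpoints numeric matrix (n x 3) of endpoint coordinates (mm).
#' @param arc an \code{\link{arcSegment}}.
#' @param binWidth histogram bin width in degrees (default 5).
#' @param mode "range" (max - min, default) or "coverage" (total width of
#'   occupied bins).
#' @return list with \code{angles}, \code{radialExtent}, \code{density}
#'   (data.frame bin, count) and \code{mode}.
#' @export
radialExtent <- function(endpoints, arc, binWidth = 5,
                         mode = c("range", "coverage")) {
  mode <- match.arg(mode)
  endpoints <- as.matrix(endpoints)
  if (nrow(endpoints) == 0L) stop("no endpoints")
  rel <- sweep(endpoints, 2, arc$center)
  a0 <- rel %*% arc$e0
  a9 <- rel %*% arc$e90
  ang <- pmin(90, pmax(0, atan2(a9, a0) * 180 / pi))
  breaks <- seq(0, 90, by = binWidth)
  bins <- cut(ang, breaks = breaks, include.lowest = TRUE)
  dens <- data.frame(bin = levels(bins), count = as.integer(table(bins)))
  ext <- if (mode == "range") max(ang) - min(ang)
         else sum(dens$count > 0) * binWidth
  list(angles = as.numeric(ang), radialExtent = as.numeric(ext),
       density = dens, mode = mode)
}

#' Angular deviation of tracked steps near branch points
#'
#' For every step of the composed pathways whose midpoint lies within
#' \code{radius} of a ground-truth branching spot, the angle between the
#' step direction and the nearest ground-truth tangent is computed
#' (sign-insensitive). At a branching spot several centerlines pass through
#' the same point, so "nearest" is resolved per centerline: every
#' centerline whose tube contains the step midpoint contributes the tangent
#' at its closest point, and the step is scored against the best-matching
#' one (a step can only follow one of the co-located bundles). Tube
#' membership is widened by half a voxel diagonal because propagation reads
#' the peaks of the containing voxel: a step just outside a tube may still
#' legitimately follow that tube's population when the voxel centre is
#' inside it. Summarizes
#' how faithfully branching directions are reconstructed.
#'
#' @param pathways list of (n x 3) matrices or a
#'   \linkS4class{MultiLevelTractogram}.
#' @param geometry a \linkS4class{BundleGeometry}.
#' @param radius neighbourhood radius around branch points, mm (default 3).
#' @param voxelHalfDiag half the voxel diagonal, mm (default 0.87 for 1 mm
#'   isotropic), added to the tube radius for membership.
#' @return list with \code{angles} (degrees, one per qualifying step) and
#'   \code{maxAngle}.
#' @export
branchAngleDeviation <- function(pathways, geometry, radius = 3,
                                 voxelHalfDiag = sqrt(3) / 2) {
  if (is(pathways, "MultiLevelTractogram"))
    pathways <- composePathways(pathways)
  nc <- length(geometry@centerlines)
  cls <- geometry@centerlines
  tgs <- lapply(cls, centerlineTangents)
  angles <- numeric(0)
  for (p in pathways) {
    if (nrow(p) < 2L) next
    step <- p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
    len <- sqrt(rowSums(step^2))
    ok <- len > 1e-9
    if (!any(ok)) next
    mid <- (p[-1, , drop = FALSE] + p[-nrow(p), , drop = FALSE])[ok, , drop = FALSE] / 2
    sd_ <- step[ok, , drop = FALSE] / len[ok]
    near <- rep(FALSE, nrow(mid))
    for (r in seq_len(nrow(geometry@branchPoints)))
      near <- near | sqrt(colSums((t(mid) - geometry@branchPoints[r, ])^2)) <= radius
    if (!any(near)) next
    mid <- mid[near, , drop = FALSE]; sd_ <- sd_[near, , drop = FALSE]
    # per centerline: distance to nearest point and angle to its tangent
    dist <- matrix(Inf, nrow(mid), nc)
    angc <- matrix(Inf, nrow(mid), nc)
    for (ci in seq_len(nc)) {
      cl <- cls[[ci]]
      D <- outer(rowSums(mid^2), rep(1, nrow(cl))) - 2 * mid %*% t(cl) +
        outer(rep(1, nrow(mid)), rowSums(cl^2))
      nearest <- max.col(-D, ties.method = "first")
      dist[, ci] <- sqrt(pmax(0, D[cbind(seq_len(nrow(D)), nearest)]))
      dots <- abs(rowSums(sd_ * tgs[[ci]][nearest, , drop = FALSE]))
      angc[, ci] <- acos(pmin(1, dots)) * 180 / pi
    }
    for (r in seq_len(nrow(mid))) {
      inTube <- which(dist[r, ] <= geometry@radii + voxelHalfDiag)
      if (!length(inTube)) inTube <- which.min(dist[r, ])
      angles <- c(angles, min(angc[r, inTube]))
    }
  }
  list(angles = angles,
       maxAngle = if (length(angles)) max(angles) else NA_real_)
}

#' Per-branch direction deviation at branching spots
#'
#' For every retained streamline and every branching spot, the step
#' directions whose midpoints fall within \code{radius} of the spot are
#' averaged (resultant of the equal-length steps) into one reconstructed
#' branch direction, which is scored against the best-matching tangent
#' among the centerlines whose tube contains the window centroid (see
#' \code{\link{branchAngleDeviation}} for the membership rule). Raw
#' streamlines are used rather than composed pathways: a composed pathway
#' turns from trunk onto branch inside the window, whereas each individual
#' streamline traverses it along a single bundle, which is the branch
#' direction the reconstruction asserts. The step-level variant is
#' \code{\link{branchAngleDeviation}}.
#'
#' @inheritParams branchAngleDeviation
#' @return list with \code{angles} (degrees, one per streamline x visited
#'   branching spot) and \code{maxAngle}.
#' @export
branchDirectionDeviation <- function(pathways, geometry, radius = 3,
                                     voxelHalfDiag = sqrt(3) / 2) {
  if (is(pathways, "MultiLevelTractogram"))
    pathways <- lapply(pathways@streamlines, slot, "points")
  nc <- length(geometry@centerlines)
  cls <- geometry@centerlines
  tgs <- lapply(cls, centerlineTangents)
  angles <- numeric(0)
  for (p in pathways) {
    if (nrow(p) < 2L) next
    step <- p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
    len <- sqrt(rowSums(step^2))
    ok <- len > 1e-9
    if (!any(ok)) next
    mid <- (p[-1, , drop = FALSE] + p[-nrow(p), , drop = FALSE])[ok, , drop = FALSE] / 2
    st <- step[ok, , drop = FALSE]
    for (r in seq_len(nrow(geometry@branchPoints))) {
      inWin <- sqrt(colSums((t(mid) - geometry@branchPoints[r, ])^2)) <= radius
      if (!any(inWin)) next
      res <- colSums(st[inWin, , drop = FALSE])
      nrm <- sqrt(sum(res^2))
      if (nrm < 1e-9) next
      dir <- res / nrm
      ctr <- colMeans(mid[inWin, , drop = FALSE])
      best <- Inf; bestDist <- Inf; bestAngAtNearest <- Inf
      for (ci in seq_len(nc)) {
        cl <- cls[[ci]]
        d2 <- colSums((t(cl) - ctr)^2)
        nearest <- which.min(d2)
        dd <- sqrt(d2[nearest])
        a <- acos(min(1, abs(sum(dir * tgs[[ci]][nearest, ])))) * 180 / pi
        if (dd <= geometry@radii[ci] + voxelHalfDiag) best <- min(best, a)
        if (dd < bestDist) { bestDist <- dd; bestAngAtNearest <- a }
      }
      angles <- c(angles, if (is.finite(best)) best else bestAngAtNearest)
    }
  }
  list(angles = angles,
       maxAngle = if (length(angles)) max(angles) else NA_real_)
}
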