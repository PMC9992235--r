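# 2D Delaunay triangulation (Bowyer-Watson). Used by the topography
# preservation index to connect nearby pathway endpoints.

# circumcircle of triangle (ax,ay),(bx,by),(cx,cy): centre + squared radius
.circumcircle <- function(ax, ay, bx, by, cx, cy) {
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(NULL)
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  c(ux, uy, (ax - ux)^2 + (ay - uy)^2)
}

#' 2D Delaunay triangulation
#'
#' Bowyer-Watson incremental triangulation. Collinear input (no valid
#' triangle) degrades to a path graph along the collinear order, flagged
#' by \code{degenerate}.
#'
#' @param xy numeric matrix (n x 2), n >= 3.
#' @return list with \code{triangles} (t x 3 vertex indices, possibly
#'   0 rows), \code{edges} (e x 2, i < j) and \code{degenerate}.
#' @export
delaunay2D <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 3L) stop("triangulation needs at least 3 points")

  # collinearity check against the best-fit line
  ctr <- colMeans(xy)
  sv <- svd(sweep(xy, 2, ctr))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) {
    ord <- order(sweep(xy, 2, ctr) %*% sv$v[, 1])
    edges <- cbind(ord[-n], ord[-1])
    edges <- t(apply(edges, 1, sort))
    return(list(triangles = matrix(integer(0), 0, 3), edges = edges,
                degenerate = TRUE))
  }

  span <- max(apply(xy, 2, function(c) diff(range(c))))
  m <- colMeans(xy)
  big <- 100 * max(span, 1)
  P <- rbind(xy,
             m + c(-big, -big), m + c(big, -big), m + c(0, big))
  tris <- list(c(n + 1L, n + 2L, n + 3L))
  circ <- list(.circumcircle(P[n + 1, 1], P[n + 1, 2], P[n + 2, 1],
                             P[n + 2, 2], P[n + 3, 1], P[n + 3, 2]))
  for (p in seq_len(n)) {
    bad <- which(vapply(circ, function(cc)
      !is.null(cc) && (P[p, 1] - cc[1])^2 + (P[p, 2] - cc[2])^2 <= cc[3] * (1 + 1e-12),
      TRUE))
    if (!length(bad)) next
    # boundary polygon: edges of bad triangles not shared by two of them
    edgeList <- do.call(rbind, lapply(tris[bad], function(t_)
      rbind(sort(t_[1:2]), sort(t_[2:3]), sort(t_[c(1, 3)]))))
    key <- paste(edgeList[, 1], edgeList[, 2])
    boundary <- edgeList[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    tris <- tris[-bad]; circ <- circ[-bad]
    for (e in seq_len(nrow(boundary))) {
      t_ <- c(boundary[e, ], p)
      cc <- .circumcircle(P[t_[1], 1], P[t_[1], 2], P[t_[2], 1], P[t_[2], 2],
                          P[t_[3], 1], P[t_[3], 2])
      if (is.null(cc)) next
      tris[[length(tris) + 1L]] <- t_
      circ[[length(circ) + 1L]] <- cc
    }
  }
  keep <- vapply(tris, function(t_) all(t_ <= n), TRUE)
  T_ <- do.call(rbind, tris[keep])
  if (is.null(T_) || nrow(T_) == 0L) {
    # numerically near-degenerate: fall back to the path graph
    ord <- order(sweep(xy, 2, ctr) %*% sv$v[, 1])
    edges <- t(apply(cbind(ord[-n], ord[-1]), 1, sort))
    return(list(triangles = matrix(integer(0), 0, 3), edges = edges,
                degenerate = TRUE))
  }
  edges <- rbind(T_[, 1:2], T_[, 2:3], T_[, c(1, 3)])
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  list(triangles = T_, edges = edges, degenerate = FALSE)
}
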