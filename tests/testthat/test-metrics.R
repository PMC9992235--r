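# TPI, MADF, radial extent, Delaunay triangulation.

.zROI <- function() projectionROI(c(0, 0, 0), diag(3), c(2, 2, 10))

# straight pathway through the ROI at offset (x, y), ending at `end`
.pathThrough <- function(z01, end) {
  # crossing position along the ROI's longest axis (z in [-5, 5])
  z <- -5 + 10 * z01
  rbind(c(0, 0, z), c(0.5, 0, z), c(end[1], end[2], end[3]))
}

test_that("identical crossing positions give TPI = 0", {
  paths <- list(.pathThrough(0.4, c(0, 0, 20)),
                .pathThrough(0.4, c(10, 0, 20)),
                .pathThrough(0.4, c(5, 8, 20)))
  expect_identical(tpi(paths, .zROI())$tpi, 0)
})

test_that("the hand-worked 3-pathway triangle gives TPI = 2/3", {
  paths <- list(.pathThrough(0, c(0, 0, 20)),
                .pathThrough(0.5, c(10, 0, 20)),
                .pathThrough(1, c(5, 8, 20)))
  res <- tpi(paths, .zROI())
  # three endpoints -> one triangle -> edges (1,2), (2,3), (1,3):
  # weights 0.5, 0.5, 1 -> mean 2/3
  expect_identical(nrow(res$edges), 3L)
  expect_equal(res$tpi, 2 / 3, tolerance = 1e-12)
})

test_that("shuffling the crossing order degrades TPI in >= 95% of trials", {
  set.seed(42)
  n <- 30
  # order-preserving configuration: endpoints along a line, v increasing
  ends <- cbind(seq(0, 29), rnorm(n, sd = 0.3), rep(20, n))
  v <- seq(0, 1, length.out = n)
  paths <- lapply(seq_len(n), function(i) .pathThrough(v[i], ends[i, ]))
  base <- tpi(paths, .zROI())
  worse <- vapply(seq_len(1000), function(trial) {
    vp <- sample(v)
    w <- abs(vp[base$edges[, 1]] - vp[base$edges[, 2]])
    mean(w) >= base$tpi
  }, TRUE)
  expect_gte(mean(worse), 0.95)
})

test_that("TPI is invariant under a rigid transformation of the scene", {
  paths <- list(.pathThrough(0.1, c(0, 0, 20)),
                .pathThrough(0.45, c(10, 0, 20)),
                .pathThrough(0.8, c(5, 8, 20)),
                .pathThrough(0.95, c(2, -6, 20)))
  base <- tpi(paths, .zROI())$tpi
  th <- 0.71
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  shift <- c(3, -2, 7)
  moved <- lapply(paths, function(p) sweep(p %*% t(R), 2, -shift))
  roiMoved <- projectionROI(R %*% c(0, 0, 0) + shift, R %*% diag(3),
                            c(2, 2, 10))
  expect_equal(tpi(moved, roiMoved)$tpi, base, tolerance = 1e-9)
})

test_that("pathways missing the ROI are excluded with a warning", {
  paths <- list(.pathThrough(0, c(0, 0, 20)),
                .pathThrough(0.5, c(10, 0, 20)),
                .pathThrough(1, c(5, 8, 20)),
                rbind(c(50, 50, 50), c(51, 50, 50), c(52, 50, 50)))
  expect_warning(res <- tpi(paths, .zROI()), "do not intersect")
  expect_identical(length(res$v), 3L)
  # fewer than 3 crossing pathways is an error
  expect_error(suppressWarnings(tpi(paths[3:4], .zROI())), "at least 3")
})

test_that("MADF identities: self-distance and flip-invariance are zero", {
  set.seed(5)
  a <- cbind(cumsum(runif(20)), sin(seq_len(20) / 3), seq_len(20) / 2)
  expect_equal(madf(a, a), 0, tolerance = 1e-12)
  expect_equal(madf(a, a[rev(seq_len(nrow(a))), ]), 0, tolerance = 1e-9)
  expect_equal(madf(a, a + 1), madf(a + 1, a), tolerance = 1e-12)
})

test_that("parallel unit-spaced segments are exactly 1 mm apart", {
  a <- rbind(c(0, 0, 0), c(1, 0, 0))
  b <- rbind(c(0, 1, 0), c(1, 1, 0))
  expect_equal(madf(a, b), 1, tolerance = 1e-12)
  # direct term (1) wins over the flipped term (sqrt(2) average > 1)
  c_ <- rbind(c(1, 1, 0), c(0, 1, 0))
  expect_equal(madf(a, c_), 1, tolerance = 1e-12)
})

test_that("MADF is scale-equivariant", {
  set.seed(6)
  a <- matrix(rnorm(30), 10, 3); a <- a[order(a[, 1]), ]
  b <- matrix(rnorm(30), 10, 3); b <- b[order(b[, 1]), ]
  expect_equal(madf(a * 3.5, b * 3.5), 3.5 * madf(a, b), tolerance = 1e-9)
})

test_that("nearest-neighbour MADF: parallel segments and matrix symmetry", {
  segs <- lapply(0:2, function(y) rbind(c(0, y, 0), c(1, y, 0)))
  nn <- nearestNeighborMADF(segs)
  expect_equal(nn$minima, c(1, 1, 1), tolerance = 1e-12)
  expect_identical(nn$distances, t(nn$distances))
  expect_error(nearestNeighborMADF(segs[1]), "at least 2")
  # identical pathways are at distance zero
  nn2 <- nearestNeighborMADF(list(segs[[1]], segs[[1]]))
  expect_equal(nn2$minima, c(0, 0), tolerance = 1e-12)
})

test_that("degenerate zero-length pathways are rejected", {
  p0 <- rbind(c(1, 1, 1), c(1, 1, 1))
  expect_error(resamplePolyline(p0), "degenerate")
  expect_error(madf(p0, rbind(c(0, 0, 0), c(1, 0, 0))), "degenerate")
})

test_that("radial extent spans the arc and degenerates correctly", {
  arc <- arcSegment(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1))
  onRays <- rbind(c(10, 0, 0), c(0, 0, 10))
  expect_equal(radialExtent(onRays, arc)$radialExtent, 90, tolerance = 1e-9)
  expect_equal(radialExtent(rbind(c(5, 0, 5)), arc)$radialExtent, 0,
               tolerance = 1e-9)
  expect_error(radialExtent(matrix(numeric(0), 0, 3), arc), "no endpoints")
})

test_that("uniform endpoints over half the arc give extent of about 45 degrees", {
  set.seed(7)
  th <- runif(1000, 0, pi / 4)          # first 45 degrees of the segment
  pts <- cbind(10 * cos(th), rnorm(1000, sd = 0.1), 10 * sin(th))
  arc <- arcSegment(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1))
  res <- radialExtent(pts, arc)
  expect_equal(res$radialExtent, 45, tolerance = 5 / 45)  # within one bin
  # density occupies only the first half of the bins
  expect_identical(sum(res$density$count[10:18]), 0L)
  # coverage mode agrees within one bin
  expect_equal(radialExtent(pts, arc, mode = "coverage")$radialExtent, 45,
               tolerance = 5 / 45)
})

test_that("radial extent ignores endpoint ordering and duplication", {
  arc <- arcSegment(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1))
  pts <- rbind(c(10, 0, 1), c(3, 0, 8), c(7, 1, 3))
  base <- radialExtent(pts, arc)$radialExtent
  expect_equal(radialExtent(pts[c(3, 1, 2), ], arc)$radialExtent, base)
  expect_equal(radialExtent(pts[c(1, 1, 2, 3, 3), ], arc)$radialExtent, base)
})

test_that("Delaunay triangulation satisfies the empty-circumcircle property", {
  set.seed(8)
  xy <- matrix(runif(60), 30, 2)
  tri <- delaunay2D(xy)
  expect_false(tri$degenerate)
  for (t_ in seq_len(nrow(tri$triangles))) {
    v <- tri$triangles[t_, ]
    cc <- mlftrack:::.circumcircle(xy[v[1], 1], xy[v[1], 2],
                                   xy[v[2], 1], xy[v[2], 2],
                                   xy[v[3], 1], xy[v[3], 2])
    d2 <- (xy[-v, 1] - cc[1])^2 + (xy[-v, 2] - cc[2])^2
    expect_true(all(d2 >= cc[3] * (1 - 1e-9)))
  }
  # every point participates in an edge
  expect_setequal(sort(unique(as.vector(tri$edges))), seq_len(30))
})

test_that("collinear endpoints fall back to a path graph", {
  xy <- cbind(seq_len(5), 2 * seq_len(5) + 1)
  tri <- delaunay2D(xy)
  expect_true(tri$degenerate)
  expect_identical(nrow(tri$edges), 4L)
})

test_that("branch direction deviation is small on the noiseless phantom", {
  run <- noiselessRun()
  dev <- branchDirectionDeviation(run$tr2, run$geom)
  expect_gt(length(dev$angles), 0)
  expect_lt(dev$maxAngle, 5)
  devStep <- branchAngleDeviation(run$tr2, run$geom)
  expect_lt(devStep$maxAngle, 5)
})
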