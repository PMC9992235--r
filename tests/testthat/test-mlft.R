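# Multi-level orchestration: branch harvesting, retention, composition.

# small synthetic scene: a 5x3x3 grid with two crossing peaks everywhere
.twoPeakScene <- function() {
  dims <- c(5L, 3L, 3L)
  affine <- diag(4); affine[1:3, 4] <- -(dims - 1) / 2
  pf <- uniformPeakField(dims, rbind(c(1, 0, 0), c(0, 0, 1)), c(0.8, 0.6),
                         affine = affine)
  list(pf = pf, affine = affine, dims = dims)
}

.manualStreamline <- function(points, usage, reached,
                              reason = "amplitude", level = 1L) {
  new("LeveledStreamline", points = points, usage = usage,
      level = level, parentId = NULL, branchPointIndex = NULL,
      reachedTarget = reached, terminationReason = reason,
      terminationReasonBackward = NA_character_)
}

test_that("target-reaching streamlines never contribute branch seeds", {
  sc <- .twoPeakScene()
  u <- data.frame(point = 1L, i = 2L, j = 1L, k = 1L, nAvailable = 2L,
                  used = 1L)
  reaching <- .manualStreamline(matrix(c(0, 0, 0), 1), u, TRUE)
  expect_identical(nrow(collectBranchSeeds(list(reaching), sc$pf)), 0L)
})

test_that("one unused peak yields exactly two seeds, one per antipodal sign", {
  sc <- .twoPeakScene()
  u <- data.frame(point = 1L, i = 2L, j = 1L, k = 1L, nAvailable = 2L,
                  used = 1L)
  s <- .manualStreamline(matrix(c(0, 0, 0), 1), u, FALSE)
  seeds <- collectBranchSeeds(list(s), sc$pf)
  expect_identical(nrow(seeds), 2L)
  expect_setequal(seeds$sign, c(1, -1))
  expect_equal(abs(seeds$dz), c(1, 1), tolerance = 1e-9)  # the unused +z peak
  expect_identical(seeds$level, c(2L, 2L))
})

test_that("a voxel whose only peak was used contributes no seeds", {
  dims <- c(3L, 3L, 3L)
  affine <- diag(4); affine[1:3, 4] <- -(dims - 1) / 2
  pf <- uniformPeakField(dims, c(1, 0, 0), 0.8, affine = affine)
  u <- data.frame(point = 1L, i = 1L, j = 1L, k = 1L, nAvailable = 1L,
                  used = 1L)
  s <- .manualStreamline(matrix(c(0, 0, 0), 1), u, FALSE)
  expect_identical(nrow(collectBranchSeeds(list(s), pf)), 0L)
})

test_that("branch seeds are deduplicated per (voxel, peak, sign) and capped", {
  sc <- .twoPeakScene()
  # two points in the same voxel: the duplicate (voxel, peak, sign) collapses
  u <- data.frame(point = c(1L, 2L), i = 2L, j = 1L, k = 1L,
                  nAvailable = 2L, used = 1L)
  s <- .manualStreamline(rbind(c(0, 0, 0), c(0.1, 0, 0)), u, FALSE)
  expect_identical(nrow(collectBranchSeeds(list(s), sc$pf)), 2L)
  expect_identical(nrow(collectBranchSeeds(list(s), sc$pf, perParentCap = 1L)),
                   1L)
})

test_that("one-level MLFT equals conventional tracking filtered by the target", {
  run <- noiselessRun()
  tr1 <- runMLFT(run$pk, run$geom@seedMask, run$target, nLevels = 1L)
  ref <- seedStreamlines(run$pk, run$geom@seedMask, seedsPerVoxel = 1L,
                         params = trackingParams(), targetMask = run$target)
  keepRef <- Filter(function(s) s@reachedTarget, ref)
  expect_identical(length(streamlines(tr1)), length(keepRef))
  expect_identical(tr1@levelsRun, 1L)
})

test_that("two levels reach every endpoint ROI; one level reaches strictly fewer", {
  run <- noiselessRun()
  reached2 <- roisReached(run$tr2, run$geom)
  expect_true(all(reached2))
  tr1 <- runMLFT(run$pk, run$geom@seedMask, run$target, nLevels = 1L)
  reached1 <- if (length(composePathways(tr1)) == 0L)
    rep(FALSE, length(run$geom@endpointROIs)) else roisReached(tr1, run$geom)
  expect_lt(sum(reached1), sum(reached2))
})

test_that("retention keeps exactly the reaching streamlines and their ancestors", {
  run <- noiselessRun()
  sl <- streamlines(run$tr2)
  for (id in names(sl)) {
    s <- sl[[id]]
    if (s@reachedTarget) next
    # a retained non-reaching streamline must have a reaching descendant
    descendants <- Filter(function(x) !is.null(x@parentId) &&
                            as.character(x@parentId) == id, sl)
    expect_true(any(vapply(descendants, slot, TRUE, "reachedTarget")))
  }
  # strict mode retains only reaching streamlines
  trS <- runMLFT(run$pk, run$geom@seedMask, run$target, nLevels = 2L,
                 retention = "strict")
  expect_true(all(vapply(streamlines(trS), slot, TRUE, "reachedTarget")))
})

test_that("level monotonicity: pathways at one level are a subset of two levels", {
  run <- noiselessRun()
  tr1 <- runMLFT(run$pk, run$geom@seedMask, run$target, nLevels = 1L)
  p1 <- composePathways(tr1)
  p2 <- composePathways(run$tr2)
  sig <- function(p) paste(round(as.vector(t(p)), 6), collapse = ",")
  expect_true(all(vapply(p1, sig, "") %in% vapply(p2, sig, "")))
})

test_that("composition: level-1 pathways unchanged, branch arithmetic holds", {
  run <- noiselessRun()
  sl <- streamlines(run$tr2)
  paths <- composePathways(run$tr2)
  for (id in names(paths)) {
    s <- sl[[id]]
    if (s@level == 1L) {
      expect_identical(paths[[id]], s@points)
    } else {
      parent <- sl[[as.character(s@parentId)]]
      expect_identical(nrow(paths[[id]]),
                       s@branchPointIndex + nrow(s@points))
      expect_equal(paths[[id]][s@branchPointIndex, ],
                   parent@points[s@branchPointIndex, ], tolerance = 1e-12)
    }
  }
})

test_that("composed pathways pass through the seed and end inside the target", {
  run <- noiselessRun()
  seedCentre <- voxelToWorld(which(maskArray(run$geom@seedMask),
                                   arr.ind = TRUE) - 1L, run$affine)
  for (p in composePathways(run$tr2)) {
    # the level-1 root is bidirectional, so the pathway starts at the tube
    # end below the seed but must pass through the seed voxel itself
    expect_lt(min(sqrt(colSums((t(p) - drop(seedCentre))^2))), 1)
    v <- containingVoxel(p[nrow(p), ], run$affine) + 1L
    expect_true(maskArray(run$target)[v[1], v[2], v[3]])
  }
})

test_that("a broken parent link is reported", {
  run <- noiselessRun()
  tr <- run$tr2
  lv2 <- names(Filter(function(s) s@level == 2L, streamlines(tr)))
  broken <- tr
  broken@streamlines <- tr@streamlines[lv2]   # drop the level-1 ancestors
  expect_error(composePathways(broken), "broken parent link")
})

test_that("MLFT run is reproducible byte for byte", {
  run <- noiselessRun()
  a <- runMLFT(run$pk, run$geom@seedMask, run$target, nLevels = 2L)
  expect_identical(serialize(a, NULL), serialize(run$tr2, NULL))
})

test_that("degenerate inputs are rejected", {
  run <- noiselessRun()
  empty <- emptyMask(run$gs, run$affine)
  expect_error(runMLFT(run$pk, run$geom@seedMask, empty), "empty target")
  expect_error(runMLFT(run$pk, empty, run$target), "empty seed")
  expect_error(runMLFT(run$pk, run$geom@seedMask, run$target, nLevels = 0L),
               "nLevels")
})
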