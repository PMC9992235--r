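# Multi-level fiber tractography: harvest branch seeds from the unused
# peaks of streamlines that failed to reach the target, track them as a new
# level, and finally retain only pathways connected to the target.

#' Collect branch seeds from non-reaching streamlines
#'
#' Only streamlines with \code{reachedTarget == FALSE} contribute. For
#' every visited point whose voxel holds at least one peak other than the
#' one consumed there, one seed is emitted per unused peak and antipodal
#' sign (the FOD cannot disambiguate sign, so both are launched and wrong
#' ones are removed by target filtering). Seeds are deduplicated per
#' (voxel, peak, sign) within a parent, ordered by descending peak
#' amplitude and capped per parent. A candidate angularly closer than the
#' peak field's \code{minSeparation} to the used peak is excluded to avoid
#' trivially re-tracing the parent.
#'
#' @param streamlineList list of \linkS4class{LeveledStreamline}.
#' @param peaks a \linkS4class{PeakField}.
#' @param ids parent ids parallel to \code{streamlineList}.
#' @param perParentCap maximum seeds per parent streamline (default 64).
#' @return data.frame with one row per branch seed: seed point (x, y, z),
#'   initial direction (dx, dy, dz), parent, branchPointIndex, level,
#'   amplitude and the (i, j, k, peak, sign) key.
#' @export
collectBranchSeeds <- function(streamlineList, peaks,
                               ids = seq_along(streamlineList),
                               perParentCap = 64L) {
  cosSep <- cos(peaks@minSeparation * pi / 180)
  rows <- list()
  for (si in seq_along(streamlineList)) {
    s <- streamlineList[[si]]
    if (s@reachedTarget) next
    u <- s@usage
    if (!nrow(u)) next
    seen <- character(0)
    parentRows <- list()
    for (r in seq_len(nrow(u))) {
      nav <- u$nAvailable[r]
      if (nav < 1L) next
      pk <- voxelPeaks(peaks, c(u$i[r], u$j[r], u$k[r]))
      used <- u$used[r]
      usedDir <- if (!is.na(used)) pk$dirs[used, ] else NULL
      for (q in seq_len(nav)) {
        if (!is.na(used) && q == used) next
        if (pk$amps[q] < peaks@threshold) next
        if (!is.null(usedDir) && abs(sum(pk$dirs[q, ] * usedDir)) > cosSep)
          next
        for (sgn in c(1, -1)) {
          key <- paste(u$i[r], u$j[r], u$k[r], q, sgn, sep = "_")
          if (key %in% seen) next
          seen <- c(seen, key)
          parentRows[[length(parentRows) + 1L]] <- data.frame(
            x = s@points[u$point[r], 1], y = s@points[u$point[r], 2],
            z = s@points[u$point[r], 3],
            dx = sgn * pk$dirs[q, 1], dy = sgn * pk$dirs[q, 2],
            dz = sgn * pk$dirs[q, 3],
            parent = ids[si], branchPointIndex = u$point[r],
            level = s@level + 1L, amplitude = pk$amps[q],
            i = u$i[r], j = u$j[r], k = u$k[r], peak = q, sign = sgn)
        }
      }
    }
    if (length(parentRows)) {
      tab <- do.call(rbind, parentRows)
      tab <- tab[order(-tab$amplitude), , drop = FALSE]
      rows[[length(rows) + 1L]] <- head(tab, perParentCap)
    }
  }
  if (!length(rows))
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      dx = numeric(0), dy = numeric(0), dz = numeric(0),
                      parent = integer(0), branchPointIndex = integer(0),
                      level = integer(0), amplitude = numeric(0),
                      i = integer(0), j = integer(0), k = integer(0),
                      peak = integer(0), sign = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run multi-level fiber tractography
#'
#' Level 1 is conventional bidirectional deterministic tracking from the
#' seed mask. Each further level propagates, unidirectionally, every branch
#' seed harvested from the previous level's non-reaching streamlines. After
#' the final level, streamlines that entered the target at any level are
#' retained together with their ancestors (or alone, with
#' \code{retention = "strict"}). By default iteration stops early once a
#' level contributes no new target-reaching streamline.
#'
#' @param peaks a \linkS4class{PeakField}.
#' @param seedMask,targetMask \linkS4class{RegionMask}s (both non-empty).
#' @param nLevels number of levels (>= 1; default 2).
#' @param params a \linkS4class{TrackingParams}.
#' @param seedsPerVoxel level-1 seeds per voxel.
#' @param perParentCap branch-seed cap per parent streamline.
#' @param levelCap global branch-seed cap per level (default 1e6).
#' @param retention "ancestors" keeps non-reaching ancestors of reaching
#'   branches; "strict" keeps only reaching streamlines.
#' @param earlyStop stop when a level adds no target-reaching streamline.
#' @return a \linkS4class{MultiLevelTractogram}.
#' @export
runMLFT <- function(peaks, seedMask, targetMask, nLevels = 2L,
                    params = trackingParams(), seedsPerVoxel = 1L,
                    perParentCap = 64L, levelCap = 1e6,
                    retention = c("ancestors", "strict"), earlyStop = TRUE) {
  retention <- match.arg(retention)
  if (nLevels < 1L) stop("nLevels must be >= 1")
  if (!any(targetMask@mask)) stop("empty target region")
  if (!any(seedMask@mask)) stop("empty seed region")

  sl <- seedStreamlines(peaks, seedMask, seedsPerVoxel, params, targetMask)
  ids <- seq_along(sl)
  names(sl) <- as.character(ids)
  counts <- data.frame(level = 1L, generated = length(sl),
                       retained = NA_integer_)
  levelsRun <- 1L

  for (L in seq_len(nLevels)[-1]) {
    prevIdx <- which(vapply(sl, function(s)
      s@level == L - 1L && !s@reachedTarget, TRUE))
    seeds <- collectBranchSeeds(sl[prevIdx], peaks,
                                ids = as.integer(names(sl)[prevIdx]),
                                perParentCap = perParentCap)
    if (nrow(seeds) > levelCap) {
      message("level ", L, ": branch seeds capped at ", levelCap)
      seeds <- head(seeds[order(-seeds$amplitude), , drop = FALSE], levelCap)
    }
    newReached <- 0L
    for (r in seq_len(nrow(seeds))) {
      b <- propagateStreamline(peaks, c(seeds$x[r], seeds$y[r], seeds$z[r]),
                               c(seeds$dx[r], seeds$dy[r], seeds$dz[r]),
                               params, targetMask, level = L,
                               parentId = seeds$parent[r],
                               branchPointIndex = seeds$branchPointIndex[r])
      if ((nrow(b@points) - 1L) * params@stepSize < params@minLength) next
      id <- length(sl) + 1L
      sl[[as.character(id)]] <- b
      if (b@reachedTarget) newReached <- newReached + 1L
    }
    counts <- rbind(counts,
                    data.frame(level = L, generated = nrow(seeds),
                               retained = NA_integer_))
    levelsRun <- L
    if (earlyStop && newReached == 0L) break
  }

  # retention: target-reaching streamlines, plus their ancestors by default
  keep <- vapply(sl, slot, TRUE, "reachedTarget")
  if (retention == "ancestors") {
    for (id in names(sl)[keep]) {
      p <- sl[[id]]@parentId
      while (!is.null(p)) {
        keep[as.character(p)] <- TRUE
        p <- sl[[as.character(p)]]@parentId
      }
    }
  }
  retained <- sl[keep]
  lv <- vapply(retained, slot, 1L, "level")
  counts$retained <- vapply(counts$level, function(L)
    sum(lv == L), 1L)

  new("MultiLevelTractogram", streamlines = retained,
      levelsRun = levelsRun, counts = counts, params = params)
}

#' Compose full seed-to-target pathways
#'
#' For every retained target-reaching streamline, parent links are walked
#' back to level 1, concatenating each parent's points from its start up to
#' the branch point with the child's points. Returns one polyline per
#' reaching leaf.
#'
#' @param tractogram a \linkS4class{MultiLevelTractogram} (retention
#'   already applied).
#' @return named list of (n x 3) point matrices, one per target-reaching
#'   streamline.
#' @export
composePathways <- function(tractogram) {
  sl <- tractogram@streamlines
  out <- list()
  for (id in names(sl)) {
    s <- sl[[id]]
    if (!s@reachedTarget) next
    pts <- s@points
    cur <- s
    while (!is.null(cur@parentId)) {
      pid <- as.character(cur@parentId)
      if (is.null(sl[[pid]]))
        stop("broken parent link: streamline ", id, " references ", pid)
      parent <- sl[[pid]]
      pts <- rbind(parent@points[seq_len(cur@branchPointIndex), , drop = FALSE],
                   pts)
      cur <- parent
    }
    out[[id]] <- pts
  }
  out
}
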