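# Reading and writing the standard formats: NIfTI volumes, FSL bval/bvec
# text files, MRtrix TCK track files with a JSON sidecar for per-streamline
# tracking metadata.

#' Convert between world (mm) and voxel coordinates
#'
#' Voxel indices are 0-based; the affine maps the centre of voxel (i, j, k)
#' to mm. \code{worldToVoxel} returns continuous voxel coordinates; the
#' containing voxel of a point is \code{round(worldToVoxel(...))}.
#'
#' @param points numeric matrix (n x 3) or length-3 vector.
#' @param affine 4x4 voxel-to-world matrix.
#' @return numeric matrix (n x 3).
#' @export
voxelToWorld <- function(points, affine) {
  p <- matrix(points, ncol = 3)
  t(affine[1:3, 1:3] %*% t(p) + affine[1:3, 4])
}

#' @rdname voxelToWorld
#' @export
worldToVoxel <- function(points, affine) {
  p <- matrix(points, ncol = 3)
  inv <- solve(affine)
  t(inv[1:3, 1:3] %*% t(p) + inv[1:3, 4])
}

#' @rdname voxelToWorld
#' @details \code{containingVoxel} rounds halves towards positive infinity
#'   (\code{floor(v + 0.5)}), matching the propagation core, so points on a
#'   voxel boundary resolve consistently everywhere.
#' @export
containingVoxel <- function(points, affine) {
  v <- floor(worldToVoxel(points, affine) + 0.5)
  storage.mode(v) <- "integer"
  v
}


# strip RNifti's class/attributes down to a plain numeric array
.asPlainArray <- function(img) {
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))
  a
}

.readNumericTable <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(x) as.numeric(strsplit(trimws(x), "\\s+")[[1]]))
  n <- unique(vapply(rows, length, 1L))
  if (length(n) != 1L) stop("ragged numeric table in ", path)
  do.call(rbind, rows)
}

# FSL dialect: bvec as 3 rows of N or N rows of 3, auto-detected by shape.
.readBvecs <- function(path, nExpected) {
  tab <- .readNumericTable(path)
  if (nrow(tab) == 3L && ncol(tab) == 3L) {
    message("bvec table is 3 x 3; assuming 3 rows of 3 volumes (FSL layout)")
    t(tab)
  } else if (nrow(tab) == 3L) {
    t(tab)
  } else if (ncol(tab) == 3L) {
    tab
  } else {
    stop("bvec table must be 3 x N or N x 3, got ", nrow(tab), " x ", ncol(tab))
  }
}

#' Read a diffusion-weighted series
#'
#' Loads a 4D NIfTI together with FSL-style bval/bvec files. Gradient
#' vectors whose norm deviates from 1 by less than 1e-3 are re-normalized;
#' larger deviations are rejected.
#'
#' @param niftiPath path to a 4D NIfTI (.nii or .nii.gz).
#' @param bvalPath,bvecPath paths to whitespace-separated b-value /
#'   b-vector text files.
#' @return a \linkS4class{DWIVolume}.
#' @export
readDWI <- function(niftiPath, bvalPath, bvecPath) {
  img <- RNifti::readNifti(niftiPath)
  sig <- .asPlainArray(img)
  if (length(dim(sig)) != 4L)
    stop("expected a 4D NIfTI, got ", length(dim(sig)), "D")
  bvals <- as.numeric(.readNumericTable(bvalPath))
  bvecs <- .readBvecs(bvecPath)
  if (nrow(bvecs) != length(bvals))
    stop(sprintf("gradient count mismatch: %d bvals vs %d bvecs",
                 length(bvals), nrow(bvecs)))
  if (length(bvals) != dim(sig)[4])
    stop(sprintf("gradient table does not match volume count: %d vs %d",
                 length(bvals), dim(sig)[4]))
  dw <- bvals > 0
  if (any(dw)) {
    nrm <- sqrt(rowSums(bvecs[dw, , drop = FALSE]^2))
    if (any(abs(nrm - 1) >= 1e-3))
      stop("bvec norms deviate from 1 by >= 1e-3; refusing to renormalize")
    bvecs[dw, ] <- bvecs[dw, , drop = FALSE] / nrm
  }
  affine <- unclass(RNifti::xform(img))[1:4, 1:4, drop = FALSE]
  attributes(affine) <- list(dim = c(4L, 4L))
  if (abs(det(affine)) < 1e-12) stop("non-invertible affine in ", niftiPath)
  new("DWIVolume", signal = sig, affine = affine,
      voxelSize = as.numeric(RNifti::pixdim(img))[1:3],
      gradients = new("GradientTable", bvals = bvals, bvecs = bvecs))
}

.writeNiftiWithAffine <- function(arr, affine, voxelSize, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxelSize
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a diffusion-weighted series
#'
#' @param dwi a \linkS4class{DWIVolume}.
#' @param niftiPath output NIfTI path.
#' @param bvalPath,bvecPath output gradient-table paths (FSL layout:
#'   single-row bvals, 3-row bvecs).
#' @return invisibly, \code{niftiPath}.
#' @export
writeDWI <- function(dwi, niftiPath, bvalPath, bvecPath) {
  .writeNiftiWithAffine(dwi@signal, dwi@affine, c(dwi@voxelSize, 1),
                        niftiPath)
  writeLines(paste(format(dwi@gradients@bvals, scientific = FALSE, trim = TRUE),
                   collapse = " "), bvalPath)
  writeLines(apply(t(dwi@gradients@bvecs), 1, function(r)
    paste(format(r, digits = 10), collapse = " ")), bvecPath)
  invisible(niftiPath)
}

#' Read a region mask on the grid of a reference volume
#'
#' Values above 0.5 become TRUE. The grid must match the reference exactly.
#'
#' @param niftiPath path to a 3D NIfTI.
#' @param reference a \linkS4class{DWIVolume} defining the expected grid.
#' @param role one of "generic", "seed", "target"; seed and target roles
#'   reject empty masks.
#' @param label mask label (defaults to the file name).
#' @return a \linkS4class{RegionMask}.
#' @export
readMask <- function(niftiPath, reference, role = c("generic", "seed", "target"),
                     label = basename(niftiPath)) {
  role <- match.arg(role)
  img <- RNifti::readNifti(niftiPath)
  arr <- .asPlainArray(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3L)
    stop("expected a 3D mask, got ", length(dim(arr)), "D")
  if (!identical(dim(arr), dim(reference@signal)[1:3]))
    stop(sprintf("mask grid %s does not match reference grid %s",
                 paste(dim(arr), collapse = "x"),
                 paste(dim(reference@signal)[1:3], collapse = "x")))
  m <- arr > 0.5
  if (!any(m) && role != "generic")
    stop("empty ", role, " region: ", niftiPath)
  new("RegionMask", mask = m, affine = reference@affine, label = label)
}

#' Write a region mask as NIfTI
#' @param mask a \linkS4class{RegionMask}.
#' @param path output path.
#' @param voxelSize voxel size in mm (default 1 mm isotropic).
#' @return invisibly, \code{path}.
#' @export
writeMask <- function(mask, path, voxelSize = c(1, 1, 1)) {
  .writeNiftiWithAffine(array(as.numeric(mask@mask), dim = dim(mask@mask)),
                        mask@affine, voxelSize, path)
}

# ---- TCK (MRtrix track file) ----

#' Write a tractogram as an MRtrix TCK file with a JSON sidecar
#'
#' Points are written as little-endian float32 triplets in world mm, one
#' NaN triplet after each streamline and an Inf triplet terminating the
#' file. TCK cannot carry per-streamline fields, so level, parent id,
#' branch point index, target flag and termination reason go to a JSON
#' sidecar keyed by streamline index.
#'
#' @param tractogram a \linkS4class{MultiLevelTractogram}, or a plain list
#'   of (n x 3) point matrices.
#' @param path output .tck path.
#' @param sidecarPath output JSON path; NULL suppresses the sidecar.
#' @return invisibly, \code{path}.
#' @export
writeTractogram <- function(tractogram, path,
                            sidecarPath = paste0(path, ".json")) {
  if (is(tractogram, "MultiLevelTractogram")) {
    pts <- lapply(tractogram@streamlines, slot, "points")
    meta <- lapply(seq_along(tractogram@streamlines), function(i) {
      s <- tractogram@streamlines[[i]]
      list(level = s@level,
           parent = if (is.null(s@parentId)) NULL else s@parentId,
           branch_point_index = if (is.null(s@branchPointIndex)) NULL
                                else s@branchPointIndex,
           reached_target = s@reachedTarget,
           termination_reason = s@terminationReason)
    })
    names(meta) <- as.character(seq_along(meta))
  } else {
    pts <- tractogram
    meta <- NULL
  }
  if (length(pts) == 0L) warning("writing an empty tractogram: ", path)

  body <- unlist(lapply(pts, function(p) c(t(p), rep(NaN, 3))))
  body <- c(body, rep(Inf, 3))

  hdr <- function(offset) {
    paste0("mrtrix tracks\n",
           "datatype: Float32LE\n",
           "count: ", length(pts), "\n",
           "file: . ", offset, "\n",
           "END\n")
  }
  offset <- nchar(hdr(0), type = "bytes")
  # offset text length can grow once the offset itself is included
  while (nchar(hdr(offset), type = "bytes") != offset)
    offset <- nchar(hdr(offset), type = "bytes")

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr(offset), con, eos = NULL)
  writeBin(body, con, size = 4L, endian = "little")
  if (!is.null(sidecarPath) && !is.null(meta))
    jsonlite::write_json(meta, sidecarPath, auto_unbox = TRUE, null = "null",
                         pretty = TRUE)
  invisible(path)
}

#' Read an MRtrix TCK file (and sidecar, if present)
#'
#' @param path .tck path.
#' @param sidecarPath JSON sidecar path; read when the file exists.
#' @return list with \code{streamlines} (list of n x 3 matrices, mm) and
#'   \code{meta} (list from the sidecar or NULL).
#' @export
readTractogram <- function(path, sidecarPath = paste0(path, ".json")) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "mrtrix tracks")) stop("not a TCK file: ", path)
  offset <- NA_integer_
  datatype <- "Float32LE"
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("unterminated TCK header in ", path)
    if (identical(line, "END")) break
    kv <- sub(":.*$", "", line)
    val <- trimws(sub("^[^:]*:", "", line))
    if (kv == "file") offset <- as.integer(sub("^\\.\\s+", "", val))
    if (kv == "datatype") datatype <- val
  }
  if (!identical(datatype, "Float32LE"))
    stop("unsupported TCK datatype: ", datatype)
  if (is.na(offset)) stop("TCK header lacks a file offset")
  seek(con, where = offset, origin = "start")
  raw <- readBin(con, "numeric", n = file.size(path), size = 4L,
                 endian = "little")
  m <- matrix(raw, ncol = 3, byrow = TRUE)
  isInf <- is.infinite(m[, 1])
  if (any(isInf)) m <- m[seq_len(which(isInf)[1] - 1L), , drop = FALSE]
  isNaN <- is.nan(m[, 1])
  ends <- which(isNaN)
  starts <- c(1L, head(ends, -1L) + 1L)
  tracks <- Map(function(s, e) m[seq(s, e - 1L), , drop = FALSE], starts, ends)
  tracks <- tracks[vapply(tracks, nrow, 1L) > 0L]
  meta <- if (!is.null(sidecarPath) && file.exists(sidecarPath))
    jsonlite::read_json(sidecarPath) else NULL
  list(streamlines = tracks, meta = meta)
}

# ---- FOD / peak NIfTI containers ----

#' Write / read an FOD field as a 4D SH-coefficient NIfTI
#'
#' @param fod a \linkS4class{FODField}.
#' @param path NIfTI path.
#' @param voxelSize voxel size in mm.
#' @return invisibly, \code{path}.
#' @export
writeFOD <- function(fod, path, voxelSize = c(1, 1, 1)) {
  .writeNiftiWithAffine(fod@coeffs, fod@affine, c(voxelSize, 1), path)
}

#' @rdname writeFOD
#' @param lmax even integer of the stored basis (inferred from the volume
#'   count when NULL).
#' @export
readFOD <- function(path, lmax = NULL) {
  img <- RNifti::readNifti(path)
  arr <- .asPlainArray(img)
  if (length(dim(arr)) != 4L) stop("expected a 4D SH-coefficient NIfTI")
  if (is.null(lmax)) lmax <- .lmaxFromCount(dim(arr)[4])
  affine <- unclass(RNifti::xform(img))[1:4, 1:4, drop = FALSE]
  attributes(affine) <- list(dim = c(4L, 4L))
  mk <- apply(arr != 0, 1:3, any)
  new("FODField", coeffs = arr, lmax = as.integer(lmax), affine = affine,
      mask = mk)
}

#' Write / read a peak field as a 4D NIfTI
#'
#' Volumes are ordered peak-major: for each of the K peak slots, three
#' direction components then one amplitude (4K volumes in total). Empty
#' slots are zero.
#'
#' @param peaks a \linkS4class{PeakField}.
#' @param path NIfTI path.
#' @param voxelSize voxel size in mm.
#' @return invisibly, \code{path}.
#' @export
writePeaks <- function(peaks, path, voxelSize = c(1, 1, 1)) {
  d <- dim(peaks@counts)
  K <- dim(peaks@amps)[4]
  arr <- array(0, dim = c(d, 4L * K))
  for (q in seq_len(K)) {
    for (c_ in 1:3) {
      v <- peaks@dirs[, , , q, c_]
      v[is.na(v)] <- 0
      arr[, , , 4L * (q - 1L) + c_] <- v
    }
    a <- peaks@amps[, , , q]
    a[is.na(a)] <- 0
    arr[, , , 4L * q] <- a
  }
  .writeNiftiWithAffine(arr, peaks@affine, c(voxelSize, 1), path)
}

#' @rdname writePeaks
#' @param threshold,minSeparation metadata restored onto the loaded field.
#' @export
readPeaks <- function(path, threshold = 0.1, minSeparation = 15) {
  img <- RNifti::readNifti(path)
  arr <- .asPlainArray(img)
  if (length(dim(arr)) != 4L || dim(arr)[4] %% 4L != 0L)
    stop("expected a 4D peak NIfTI with 4K volumes")
  K <- dim(arr)[4] %/% 4L
  d <- dim(arr)[1:3]
  affine <- unclass(RNifti::xform(img))[1:4, 1:4, drop = FALSE]
  attributes(affine) <- list(dim = c(4L, 4L))
  dirs <- array(NA_real_, dim = c(d, K, 3))
  amps <- array(NA_real_, dim = c(d, K))
  counts <- array(0L, dim = d)
  for (q in seq_len(K)) {
    a <- arr[, , , 4L * q]
    present <- a > 0
    counts <- counts + as.integer(present)
    a[!present] <- NA
    amps[, , , q] <- a
    for (c_ in 1:3) {
      v <- arr[, , , 4L * (q - 1L) + c_]
      v[!present] <- NA
      dirs[, , , q, c_] <- v
    }
  }
  new("PeakField", dirs = dirs, amps = amps, counts = counts,
      affine = affine, threshold = threshold, minSeparation = minSeparation)
}
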