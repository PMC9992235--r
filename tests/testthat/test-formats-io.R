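# NIfTI / bval / bvec / TCK input-output.

.tinyDWI <- function() {
  set.seed(9)
  gdirs <- repulsionDirections(8, seed = 3L)
  sig <- array(abs(rnorm(4 * 4 * 3 * 10, mean = 50, sd = 5)),
               dim = c(4, 4, 3, 10))
  affine <- diag(4); affine[1:3, 4] <- c(-2, -2, -1)
  new("DWIVolume", signal = sig, affine = affine, voxelSize = c(1, 1, 1),
      gradients = new("GradientTable",
                      bvals = c(0, 0, rep(1000, 8)),
                      bvecs = rbind(matrix(0, 2, 3), gdirs)))
}

test_that("DWI write-then-read is an identity within float tolerance", {
  dwi <- .tinyDWI()
  td <- withr::local_tempdir()
  writeDWI(dwi, file.path(td, "dwi.nii.gz"), file.path(td, "bvals"),
           file.path(td, "bvecs"))
  back <- readDWI(file.path(td, "dwi.nii.gz"), file.path(td, "bvals"),
                  file.path(td, "bvecs"))
  expect_equal(signalArray(back), signalArray(dwi), tolerance = 1e-6)
  expect_equal(affineMatrix(back), affineMatrix(dwi), tolerance = 1e-6)
  expect_equal(bValues(back), bValues(dwi), tolerance = 1e-6)
  expect_equal(unname(bVectors(back)), unname(bVectors(dwi)),
               tolerance = 1e-6)
})

test_that("bvec norms near 1 are renormalized, far from 1 rejected", {
  dwi <- .tinyDWI()
  td <- withr::local_tempdir()
  writeDWI(dwi, file.path(td, "dwi.nii.gz"), file.path(td, "bvals"),
           file.path(td, "bvecs"))
  bv <- t(bVectors(dwi))
  bv[, 3] <- bv[, 3] * 0.9995           # norm 0.9995: renormalize
  writeLines(apply(bv, 1, paste, collapse = " "), file.path(td, "bvecs2"))
  back <- readDWI(file.path(td, "dwi.nii.gz"), file.path(td, "bvals"),
                  file.path(td, "bvecs2"))
  expect_equal(sqrt(sum(bVectors(back)[3, ]^2)), 1, tolerance = 1e-9)

  bv[, 3] <- bv[, 3] * 0.5              # norm far from 1: reject
  writeLines(apply(bv, 1, paste, collapse = " "), file.path(td, "bvecs3"))
  expect_error(readDWI(file.path(td, "dwi.nii.gz"), file.path(td, "bvals"),
                       file.path(td, "bvecs3")), "refusing")
})

test_that("a gradient count mismatch is reported with both counts", {
  dwi <- .tinyDWI()
  td <- withr::local_tempdir()
  writeDWI(dwi, file.path(td, "dwi.nii.gz"), file.path(td, "bvals"),
           file.path(td, "bvecs"))
  writeLines(paste(rep(0, 66), collapse = " "), file.path(td, "bvals66"))
  writeLines(apply(matrix(0, 3, 66), 1, paste, collapse = " "),
             file.path(td, "bvecs66"))
  expect_error(readDWI(file.path(td, "dwi.nii.gz"), file.path(td, "bvals66"),
                       file.path(td, "bvecs66")), "66 vs 10")
})

test_that("mask loading thresholds at 0.5 and rejects empty seed/target", {
  dwi <- .tinyDWI()
  td <- withr::local_tempdir()
  arr <- array(0, dim = c(4, 4, 3))
  arr[2, 2, 2] <- 0.6; arr[3, 3, 2] <- 0.4
  mlftrack:::.writeNiftiWithAffine(arr, affineMatrix(dwi), c(1, 1, 1, 1),
                                   file.path(td, "m.nii.gz"))
  m <- readMask(file.path(td, "m.nii.gz"), dwi)
  expect_identical(sum(maskArray(m)), 1L)
  expect_true(maskArray(m)[2, 2, 2])
  expect_false(maskArray(m)[3, 3, 2])

  mlftrack:::.writeNiftiWithAffine(array(0, dim = c(4, 4, 3)),
                                   affineMatrix(dwi), c(1, 1, 1, 1),
                                   file.path(td, "empty.nii.gz"))
  expect_error(readMask(file.path(td, "empty.nii.gz"), dwi, role = "target"),
               "empty target")
  # shape mismatch is a hard error
  mlftrack:::.writeNiftiWithAffine(array(1, dim = c(2, 2, 2)),
                                   affineMatrix(dwi), c(1, 1, 1, 1),
                                   file.path(td, "small.nii.gz"))
  expect_error(readMask(file.path(td, "small.nii.gz"), dwi), "does not match")
})

test_that("TCK layout: one NaN separator per streamline plus an Inf terminator", {
  td <- withr::local_tempdir()
  tracks <- list(matrix(as.numeric(1:9), 3, 3, byrow = TRUE),
                 matrix(as.numeric(10:18), 3, 3, byrow = TRUE))
  f <- file.path(td, "t.tck")
  writeTractogram(tracks, f, sidecarPath = NULL)
  con <- file(f, "rb")
  hdr <- character()
  repeat { l <- readLines(con, 1); hdr <- c(hdr, l); if (l == "END") break }
  offset <- as.integer(sub("^file: \\. ", "", grep("^file:", hdr, value = TRUE)))
  seek(con, offset)
  raw <- readBin(con, "numeric", n = 100, size = 4, endian = "little")
  close(con)
  m <- matrix(raw, ncol = 3, byrow = TRUE)
  expect_identical(sum(is.nan(m[, 1])), 2L)
  expect_identical(sum(is.infinite(m[, 1])), 1L)
  expect_true(is.infinite(m[nrow(m), 1]))
})

test_that("TCK round-trip preserves coordinates at float32 precision", {
  td <- withr::local_tempdir()
  set.seed(10)
  tracks <- lapply(1:3, function(i) matrix(rnorm(12, sd = 40), 4, 3))
  f <- file.path(td, "t.tck")
  writeTractogram(tracks, f, sidecarPath = NULL)
  back <- readTractogram(f, sidecarPath = NULL)
  expect_identical(length(back$streamlines), 3L)
  for (i in 1:3)
    expect_equal(back$streamlines[[i]], tracks[[i]], tolerance = 1e-5)
})

test_that("the sidecar carries level, parent and target metadata", {
  run <- noiselessRun()
  td <- withr::local_tempdir()
  f <- file.path(td, "mlft.tck")
  writeTractogram(run$tr2, f)
  back <- readTractogram(f)
  sl <- streamlines(run$tr2)
  expect_identical(length(back$streamlines), length(sl))
  lv2 <- which(vapply(sl, slot, 1L, "level") == 2L)[1]
  meta <- back$meta[[lv2]]
  expect_identical(meta$level, 2L)
  expect_identical(meta$parent, sl[[lv2]]@parentId)
  expect_true(is.logical(meta$reached_target))
})

test_that("an empty tractogram writes a valid zero-track file with a warning", {
  td <- withr::local_tempdir()
  f <- file.path(td, "empty.tck")
  expect_warning(writeTractogram(list(), f, sidecarPath = NULL), "empty")
  back <- readTractogram(f, sidecarPath = NULL)
  expect_identical(length(back$streamlines), 0L)
})

test_that("written TCK files load in an independent established reader", {
  td <- withr::local_tempdir()
  set.seed(11)
  tracks <- lapply(1:2, function(i) matrix(rnorm(15, sd = 20), 5, 3))
  f <- file.path(td, "t.tck")
  writeTractogram(tracks, f, sidecarPath = NULL)
  script <- sprintf(
    "import nibabel as nib, numpy as np\nt = nib.streamlines.load(%s)\nprint(len(t.streamlines))\nnp.save(%s, np.concatenate([np.asarray(s) for s in t.streamlines]))",
    shQuote(f), shQuote(file.path(td, "pts.npy")))
  writeLines(script, file.path(td, "check.py"))
  out <- system2("python", file.path(td, "check.py"), stdout = TRUE)
  expect_identical(tail(out, 1), "2")
  # compare coordinates through the independent reader
  script2 <- sprintf(
    "import numpy as np\nx = np.load(%s)\nnp.savetxt(%s, x)",
    shQuote(file.path(td, "pts.npy")), shQuote(file.path(td, "pts.txt")))
  writeLines(script2, file.path(td, "conv.py"))
  system2("python", file.path(td, "conv.py"))
  ref <- as.matrix(read.table(file.path(td, "pts.txt")))
  expect_equal(unname(ref), unname(do.call(rbind, tracks)), tolerance = 1e-4)
})

test_that("peak and FOD NIfTI containers round-trip", {
  run <- noiselessRun()
  td <- withr::local_tempdir()
  writeFOD(run$fod, file.path(td, "fod.nii.gz"))
  fod2 <- readFOD(file.path(td, "fod.nii.gz"))
  expect_equal(fod2@coeffs, run$fod@coeffs, tolerance = 1e-6)
  expect_identical(fod2@lmax, 8L)
  writePeaks(run$pk, file.path(td, "pk.nii.gz"))
  pk2 <- readPeaks(file.path(td, "pk.nii.gz"))
  expect_identical(nPeaks(pk2), nPeaks(run$pk))
  v <- which(nPeaks(run$pk) > 0, arr.ind = TRUE)[1, ] - 1L
  a <- voxelPeaks(run$pk, v); b <- voxelPeaks(pk2, v)
  expect_equal(a$dirs, b$dirs, tolerance = 1e-6)
  expect_equal(a$amps, b$amps, tolerance = 1e-6)
})
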