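test_that("DICOM rescale calibration maps stored values to HU exactly once", {
  vol <- ctVolume(array(0, c(4, 8, 8)))  # HU 0 -> stored 1024 at slope 1/-1024
  td <- withr::local_tempdir()
  writeDicomSeries(vol, td)
  tags <- elvarkit:::.readDicomFile(list.files(td, full.names = TRUE)[1])
  stored <- readBin(tags[["7FE0,0010"]]$bytes, "integer", 64, size = 2,
                    signed = TRUE, endian = "little")
  expect_true(all(stored == 1024L))
  v2 <- loadCTSeries(td)
  expect_equal(max(abs(v2@data)), 0)
  expect_equal(v2@sourceMeta$rescaleIntercept, -1024)
})

test_that("DICOM series loading is independent of on-disk file order", {
  ph <- cachedPhantom(phantomSpec(shape = c(8L, 24L, 24L),
                                  vessel = list(nBranches = 3L), seed = 3L))
  td <- withr::local_tempdir()
  writeDicomSeries(ph$volume, td)
  v1 <- loadCTSeries(td)
  fs <- list.files(td, full.names = TRUE)
  set.seed(7)
  invisible(file.rename(fs, file.path(td, sprintf("%s.dcm",
                                                  sample(letters[seq_along(fs)])))))
  v2 <- loadCTSeries(td)
  expect_identical(v2@data, v1@data)
  expect_identical(v2@slicePositions, v1@slicePositions)
})

test_that("phantom volume survives a DICOM write/read round trip voxelwise", {
  ph <- cachedPhantom(phantomSpec(shape = c(8L, 24L, 24L),
                                  vessel = list(nBranches = 3L), seed = 3L))
  td <- withr::local_tempdir()
  writeDicomSeries(ph$volume, td)
  v2 <- loadCTSeries(td)
  expect_equal(max(abs(v2@data - ph$volume@data)), 0)
  expect_equal(v2@spacing, ph$volume@spacing)
})

test_that("malformed DICOM input is rejected with informative errors", {
  vol <- ctVolume(array(-500, c(4, 8, 8)))
  td <- withr::local_tempdir()
  writeDicomSeries(vol, td)

  # fewer than 3 slices
  td2 <- withr::local_tempdir()
  file.copy(list.files(td, full.names = TRUE)[1:2], td2)
  expect_error(loadCTSeries(td2), "at least 3")

  # mixed series
  td3 <- withr::local_tempdir()
  file.copy(list.files(td, full.names = TRUE), td3)
  v2 <- ctVolume(array(-500, c(4, 8, 8)), origin = c(100, 0, 0))
  writeDicomSeries(v2, file.path(td3, "other"), seriesUID = "1.2.3.4")
  file.copy(list.files(file.path(td3, "other"), full.names = TRUE)[1],
            file.path(td3, "x_extra.dcm"))
  unlink(file.path(td3, "other"), recursive = TRUE)
  expect_error(loadCTSeries(td3), "mixed series")

  # duplicate slice positions
  td4 <- withr::local_tempdir()
  fs <- list.files(td, full.names = TRUE)
  file.copy(fs, td4)
  file.copy(fs[2], file.path(td4, "dup.dcm"))
  expect_error(loadCTSeries(td4), "duplicate")

  # missing rescale tags named after the offending file
  td5 <- withr::local_tempdir()
  file.copy(fs, td5)
  els <- list(
    list(group = 0x0008, element = 0x0060, vr = "CS", value = "CT"),
    list(group = 0x0020, element = 0x000E, vr = "UI", value = "1.2.9"),
    list(group = 0x0020, element = 0x1041, vr = "DS", value = "99"),
    list(group = 0x0028, element = 0x0010, vr = "US", value = 8L),
    list(group = 0x0028, element = 0x0011, vr = "US", value = 8L),
    list(group = 0x0028, element = 0x0100, vr = "US", value = 16L),
    list(group = 0x7FE0, element = 0x0010, vr = "OW",
         value = as.raw(rep(0L, 128L))))
  elvarkit:::.writeDicomFile(file.path(td5, "norescale.dcm"), els, "1.2.9.1")
  expect_error(loadCTSeries(td5), "norescale")

  # gap larger than twice the modal spacing
  td6 <- withr::local_tempdir()
  v6 <- ctVolume(array(-500, c(8, 8, 8)))
  writeDicomSeries(v6, td6)
  unlink(list.files(td6, full.names = TRUE)[4:5])  # 3x modal gap
  expect_error(loadCTSeries(td6), "gap")
})

test_that("NIfTI round trip preserves data, spacing and origin", {
  ph <- cachedPhantom(phantomSpec(shape = c(8L, 24L, 24L),
                                  vessel = list(nBranches = 3L), seed = 3L))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  saveNifti(ph$volume, f)
  v2 <- loadNifti(f)
  expect_identical(v2@data, ph$volume@data)
  expect_equal(v2@spacing, ph$volume@spacing, tolerance = 1e-6)

  va <- ctVolume(array(rnorm(120), c(6, 5, 4)), spacing = c(1.0, 0.7, 0.7),
                 origin = c(2, 3, 4))
  f2 <- withr::local_tempfile(fileext = ".nii")
  saveNifti(va, f2)
  v3 <- loadNifti(f2)
  expect_equal(v3@spacing, c(1.0, 0.7, 0.7), tolerance = 1e-6)
  expect_equal(v3@origin, c(2, 3, 4), tolerance = 1e-6)
})

test_that("4-D NIfTI input is rejected", {
  f <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), f)
  expect_error(loadNifti(f), "3-D")
})

test_that("mask save/load round trips losslessly in every format", {
  d <- c(5L, 16L, 16L)
  empty <- binaryMask(array(FALSE, d))
  rnd <- elvarkit:::.withSeed(7L,
    binaryMask(array(stats::runif(prod(d)) > 0.5, d), role = "interstitium"))
  for (m in list(empty, rnd)) {
    fn <- withr::local_tempfile(fileext = ".nii.gz")
    saveMask(m, fn)
    expect_identical(loadMask(fn)@data, m@data)
    fr <- withr::local_tempfile(fileext = ".rds")
    saveMask(m, fr, format = "rds")
    back <- loadMask(fr)
    expect_identical(back@data, m@data)
    expect_identical(back@role, m@role)
  }
  expect_identical(voxelCount(loadMask({
    fn <- withr::local_tempfile(fileext = ".nii")
    saveMask(empty, fn); fn
  })), 0L)
})

test_that("unsupported or mismatched mask formats raise errors", {
  m <- binaryMask(array(FALSE, c(3, 4, 4)))
  expect_error(saveMask(m, "x.foo", format = "foo"), "supported formats")
  expect_error(saveMask(m, "x.nii", format = "rds"), "does not match")
  expect_error(saveMask(m, "x.rds", format = "nifti"), "does not match")
})
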