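test_that("DICOM round trip preserves pixels, bit metadata and acquisition tags", {
  sp <- tiny_spec(noise_sigma = 80,
                  acquisition = list(slice_thickness_mm = 4,
                                     repetition_time_ms = 1500,
                                     echo_time_ms = 90))
  img <- generate_phantom(sp)$image
  for (ts in c("implicit", "explicit")) {
    path <- withr::local_tempfile(fileext = ".dcm")
    write_dicom(img, path, transfer_syntax = ts)
    back <- read_dicom(path)
    expect_identical(back$pixels, img$pixels, info = ts)
    expect_equal(back$bits_allocated, 16L)
    expect_equal(back$bits_stored, 12L)
    expect_equal(back$acquisition[names(img$acquisition)], img$acquisition)
  }
})

test_that("absent acquisition tags stay absent after a round trip", {
  img <- image2d(matrix(0:99, 10, 10), bits_allocated = 16L)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_dicom(img, path)
  expect_length(read_dicom(path)$acquisition, 0)
})

test_that("pydicom independently agrees with the writer", {
  img <- generate_phantom(tiny_spec(noise_sigma = 60))$image
  path <- withr::local_tempfile(fileext = ".dcm")
  write_dicom(img, path, transfer_syntax = "explicit")
  script <- paste(
    "import sys, pydicom",
    "d = pydicom.dcmread(sys.argv[1])",
    "a = d.pixel_array",
    "print(a.shape[0], a.shape[1], int(a.sum()), int(d.BitsStored))",
    sep = "; ")
  out <- system2("python", c("-c", shQuote(script), shQuote(path)),
                 stdout = TRUE)
  vals <- as.numeric(strsplit(out, " ")[[1]])
  expect_equal(vals, c(nrow(img$pixels), ncol(img$pixels),
                       sum(img$pixels), 12))
})

test_that("truncated and non-DICOM files raise errors, never partial images", {
  img <- generate_phantom(tiny_spec())$image
  path <- withr::local_tempfile(fileext = ".dcm")
  write_dicom(img, path)
  r <- readBin(path, "raw", file.info(path)$size)
  trunc_path <- withr::local_tempfile(fileext = ".dcm")
  writeBin(r[1:(length(r) - 1000)], trunc_path)
  expect_error(read_dicom(trunc_path), "truncated")
  bad <- withr::local_tempfile()
  writeBin(charToRaw("definitely not dicom"), bad)
  expect_error(read_dicom(bad), "not a DICOM")
})

test_that("compressed transfer syntaxes are refused explicitly", {
  img <- image2d(matrix(1:16, 4, 4), bits_allocated = 16L)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_dicom(img, path, transfer_syntax = "explicit")
  r <- readBin(path, "raw", file.info(path)$size)
  uid <- charToRaw("1.2.840.10008.1.2.1")
  hit <- NULL
  for (i in seq_len(length(r) - length(uid))) {
    if (all(r[i:(i + length(uid) - 1)] == uid) && r[i + length(uid)] == 0) {
      hit <- i; break
    }
  }
  expect_false(is.null(hit))
  r[hit + length(uid) - 1] <- charToRaw("4")  # JPEG family UID prefix
  patched <- withr::local_tempfile(fileext = ".dcm")
  writeBin(r, patched)
  expect_error(read_dicom(patched), "unsupported transfer syntax")
})

test_that("usable-bit audit follows the max-value convention", {
  r12 <- measure_usable_bits(image2d(matrix(c(0, 4095), 1, 2), 16L, 16L))
  expect_equal(r12$usable_bits_measured, 12)
  expect_equal(r12$span_levels, 4096)
  expect_true(r12$discrepancy)   # reported 16, measured 12

  r8 <- measure_usable_bits(image2d(matrix(c(0, 255), 1, 2), 16L, 8L))
  expect_equal(r8$usable_bits_measured, 8)
  expect_equal(r8$span_levels, 256)
  expect_false(r8$discrepancy)

  r0 <- measure_usable_bits(image2d(matrix(0, 3, 3), 16L))
  expect_equal(r0$usable_bits_measured, 1)
  expect_equal(r0$span_levels, 1)
  expect_equal(r0$occupied_levels, 1)
})

test_that("bit audit is invariant under transposition and flips", {
  px <- matrix(sample(0:4095, 100, replace = TRUE), 10, 10)
  img <- image2d(px, 16L, 12L)
  ref <- measure_usable_bits(img)
  for (tr in list(t(px), px[nrow(px):1, ], px[, ncol(px):1])) {
    got <- measure_usable_bits(image2d(tr, 16L, 12L))
    expect_equal(got[c("max_value", "min_value", "occupied_levels",
                       "span_levels", "usable_bits_measured")],
                 ref[c("max_value", "min_value", "occupied_levels",
                       "span_levels", "usable_bits_measured")])
  }
})

test_that("lsb_shift conversion shifts by measured (not reported) bits", {
  img <- image2d(matrix(c(0, 1000, 4095, 2048), 2, 2), 16L, 16L)
  out <- to_8bit(img, "lsb_shift")  # measured 12 bits -> shift 4
  expect_equal(out$pixels, matrix(c(0, 1000, 4095, 2048) %/% 16, 2, 2))
  expect_equal(max(out$pixels), 255)
  img16 <- image2d(matrix(c(0, 65535), 1, 2), 16L)
  expect_equal(max(to_8bit(img16)$pixels), 255)
})

test_that("lsb_shift is monotone non-decreasing in input value", {
  set.seed(11)
  v <- sort(sample(0:4095, 300))
  img <- image2d(matrix(v, 1), 16L, 12L)
  out <- as.integer(to_8bit(img, "lsb_shift")$pixels)
  expect_true(all(diff(out) >= 0))
})

test_that("constant images stay constant (with a rescale warning)", {
  img <- image2d(matrix(4095, 3, 3), 16L, 12L)
  expect_equal(unique(as.integer(to_8bit(img, "lsb_shift")$pixels)), 255)
  expect_warning(z <- to_8bit(img, "linear_rescale"), "constant")
  expect_true(all(z$pixels == 0))
})

test_that("acquisition criteria use closed intervals and flag absences", {
  ok <- image2d(matrix(0, 2, 2), 16L, acquisition = list(
    slice_thickness_mm = 4, repetition_time_ms = 1000, echo_time_ms = 50,
    imaging_frequency_mhz = 100, pixel_bandwidth_hz = 500))
  expect_true(check_acquisition_criteria(ok)$pass)

  thick <- ok; thick$acquisition$slice_thickness_mm <- 6
  res <- check_acquisition_criteria(thick)
  expect_false(res$pass)
  expect_equal(res$failures, "slice_thickness_mm")

  boundary <- ok; boundary$acquisition$repetition_time_ms <- 2100
  expect_true(check_acquisition_criteria(boundary)$pass)

  partial <- image2d(matrix(0, 2, 2), 16L,
                     acquisition = list(slice_thickness_mm = 4))
  res2 <- check_acquisition_criteria(partial)
  expect_true(res2$pass)
  expect_setequal(res2$unverified,
                  c("repetition_time_ms", "echo_time_ms",
                    "imaging_frequency_mhz", "pixel_bandwidth_hz"))
})

test_that("8-bit BMP round trips, including non-multiple-of-4 widths", {
  set.seed(3)
  px <- matrix(sample(0:255, 30 * 13, replace = TRUE), nrow = 30, ncol = 13)
  img <- image2d(px, bits_allocated = 8L)
  path <- withr::local_tempfile(fileext = ".bmp")
  write_bmp(img, path)
  expect_identical(read_bmp(path)$pixels, px)
  expect_error(write_bmp(image2d(matrix(0, 2, 2), 16L), tempfile()), "8-bit")
})
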