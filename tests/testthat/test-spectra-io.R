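# Data model, table round trips, ROI reduction, ENVI reading.

test_that("spectra table round trip is exact and shapes are validated", {
  set <- simulate_set(default_config(11))
  expect_equal(dim(set$intensities), c(288, 104))
  expect_equal(unname(table(set$labels)), rep(48, 6), ignore_attr = TRUE)

  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_table(set, path)
  expect_equal(length(readLines(path)), 289)  # header + 6 x 48 rows
  back <- read_spectra_table(path)
  expect_identical(back$intensities, unname(set$intensities))
  expect_identical(back$labels, set$labels)
  expect_identical(back$fractions, set$fractions)
  expect_identical(back$sample_ids, set$sample_ids)
  expect_identical(back$grid$wavelengths_nm, set$grid$wavelengths_nm)
})

test_that("single-sample and empty tables read back faithfully", {
  one <- subset_samples(tiny_set(), 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_table(one, path)
  expect_equal(nrow(read_spectra_table(path)$intensities), 1)

  empty <- spectrum_set(default_grid(), matrix(0, 0, 104),
                        integer(0), numeric(0))
  write_spectra_table(empty, path)
  expect_equal(length(readLines(path)), 1)
  expect_equal(nrow(read_spectra_table(path)$intensities), 0)
})

test_that("malformed tables raise targeted errors", {
  set <- tiny_set()
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_table(set, path)

  lines <- readLines(path)
  hdr <- strsplit(lines[1], ",")[[1]]
  hdr[5] <- hdr[4]                       # duplicate wavelength header
  writeLines(c(paste(hdr, collapse = ","), lines[-1]), path)
  expect_error(read_spectra_table(path), class = "format_error")

  writeLines(sub("^s3,", "s3,not-a-number,", sub("^s3,[0-9]+,", "s3,", lines)), path)
  expect_error(read_spectra_table(path), "row 3", class = "parse_error")

  bad <- lines
  bad[2] <- sub("^s1,0,", "s1,7,", bad[2])   # label outside 0..5
  writeLines(bad, path)
  expect_error(read_spectra_table(path), class = "validation_error")

  cells <- strsplit(lines[3], ",")[[1]]
  cells[6] <- "oops"
  bad <- lines; bad[3] <- paste(cells, collapse = ",")
  writeLines(bad, path)
  err <- tryCatch(read_spectra_table(path), error = identity)
  expect_s3_class(err, "parse_error")
  expect_match(conditionMessage(err), "row 2")
})

test_that("set validation enforces the label-fraction mixing map", {
  g <- wavelength_grid(seq(500, 900, length.out = 5))
  X <- matrix(1, 2, 5)
  expect_error(spectrum_set(g, X, c(0L, 1L), c(0, 0.2)),
               class = "validation_error")
  expect_error(spectrum_set(g, X, c(0L, 6L), c(0, 0.6)),
               class = "validation_error")
  expect_error(spectrum_set(g, -X, c(0L, 1L), c(0, 0.1)),
               class = "validation_error")
  expect_silent(spectrum_set(g, -X, c(0L, 1L), c(0, 0.1), preprocessed = TRUE))
})

test_that("roi_mean_spectrum matches hand values and the pixel-loop oracle", {
  g <- wavelength_grid(seq(480, 520, length.out = 5))
  cube <- hypercube(array(7, c(4, 6, 5)), g)
  roi <- rect_roi(1, 3, 2, 5)
  expect_equal(roi_mean_spectrum(cube, roi), rep(7, 5))

  arr <- array(0, c(3, 3, 5))
  arr[1:2, 1:2, 1] <- c(1, 2, 3, 4)
  cube <- hypercube(arr, g)
  expect_equal(roi_mean_spectrum(cube, rect_roi(0, 2, 0, 2))[1], 2.5)

  set.seed(5)
  arr <- array(rnorm(4 * 5 * 5), c(4, 5, 5))
  cube <- hypercube(arr, g)
  full <- rect_roi(0, 4, 0, 5)
  expect_equal(roi_mean_spectrum(cube, full), oracle_roi_mean(cube, full))
  sub <- rect_roi(1, 3, 2, 5)
  expect_equal(roi_mean_spectrum(cube, sub), oracle_roi_mean(cube, sub))
})

test_that("roi_mean_spectrum is linear in the cube and bounds-checked", {
  g <- wavelength_grid(seq(480, 520, length.out = 3))
  set.seed(6)
  a1 <- array(rnorm(24), c(4, 2, 3)); a2 <- array(rnorm(24), c(4, 2, 3))
  roi <- rect_roi(0, 3, 0, 2)
  lhs <- roi_mean_spectrum(hypercube(2 * a1 - 3 * a2, g), roi)
  rhs <- 2 * roi_mean_spectrum(hypercube(a1, g), roi) -
    3 * roi_mean_spectrum(hypercube(a2, g), roi)
  expect_equal(lhs, rhs)
  expect_error(roi_mean_spectrum(hypercube(a1, g), rect_roi(0, 5, 0, 2)),
               class = "bounds_error")
  expect_error(rect_roi(2, 2, 0, 1), class = "bounds_error")
})

test_that("ENVI cubes round-trip through the reader in all interleaves", {
  g_wl <- seq(475, 1000, length.out = 6)
  set.seed(8)
  arr <- array(round(rnorm(4 * 3 * 6), 4), c(4, 3, 6))  # rows x cols x bands
  for (il in c("bsq", "bil", "bip")) {
    base <- withr::local_tempfile()
    hdr <- paste0(base, ".hdr")
    body <- switch(il,
      bsq = as.numeric(aperm(arr, c(2, 1, 3))),
      bil = as.numeric(aperm(arr, c(2, 3, 1))),
      bip = as.numeric(aperm(arr, c(3, 2, 1))))
    writeBin(body, paste0(base, ".img"), size = 8, endian = "little")
    writeLines(c("ENVI", "samples = 3", "lines = 4", "bands = 6",
                 "data type = 5", paste("interleave =", il), "byte order = 0",
                 paste0("wavelength = {", paste(g_wl, collapse = ", "), "}")),
               hdr)
    cube <- read_envi(hdr)
    expect_equal(cube$data, arr, info = il)
    expect_equal(cube$grid$wavelengths_nm, g_wl)
  }
})
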