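make_test_stack <- function(nz = 4, ny = 5, nx = 7, spacing = c(30, 10, 10)) {
  # distinct dimension sizes guard against axis transposition
  image_stack(array(as.numeric(seq_len(nz * ny * nx)), dim = c(nz, ny, nx)),
              spacing = spacing)
}

test_that("stacks round trip through multi-page TIFF in all supported formats", {
  stack <- make_test_stack()
  for (fmt in c("uint8", "uint16", "float32")) {
    path <- withr::local_tempfile(fileext = ".tif")
    write_stack(stack, path, format = fmt)
    back <- read_stack(path, spacing = stack$spacing)
    expect_equal(back$voxels, stack$voxels, ignore_attr = FALSE,
                 tolerance = if (fmt == "float32") 1e-6 else 0)
    expect_equal(back$spacing, stack$spacing)
  }
  # non-integer data round trips through float32 within single precision
  stack2 <- image_stack(array(runif(60), dim = c(3, 4, 5)), spacing = c(30, 10, 10))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(stack2, path)
  back2 <- read_stack(path, spacing = stack2$spacing)
  expect_equal(back2$voxels, stack2$voxels, tolerance = 1e-6)
})

test_that("single-page TIFF reads as a stack with z-dimension 1", {
  stack <- image_stack(array(as.numeric(1:20), dim = c(1, 4, 5)), spacing = c(30, 10, 10))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(stack, path, format = "uint16")
  back <- read_stack(path, spacing = c(30, 10, 10))
  expect_equal(dim(back$voxels), c(1L, 4L, 5L))
  expect_equal(back$voxels, stack$voxels)
})

test_that("axis order (z, y, x) survives the write/read cycle voxel-for-voxel", {
  stack <- make_test_stack(nz = 3, ny = 4, nx = 5)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(stack, path, format = "uint16")
  back <- read_stack(path, spacing = stack$spacing)
  for (iz in 1:3) for (iy in 1:4) for (ix in 1:5)
    expect_identical(back$voxels[iz, iy, ix], stack$voxels[iz, iy, ix])
})

test_that("TIFF interchange agrees with an independent reader/writer (tifffile)", {
  py <- Sys.which("python")
  stack <- make_test_stack(nz = 3, ny = 6, nx = 4)
  ours <- withr::local_tempfile(fileext = ".tif")
  write_stack(stack, ours, format = "uint16")

  script <- withr::local_tempfile(fileext = ".py")
  theirs <- withr::local_tempfile(fileext = ".tif")
  out_csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "import sys, numpy as np, tifffile",
    sprintf("a = tifffile.imread(%s)", shQuote(ours)),
    "np.savetxt(sys.argv[1], a.reshape(a.shape[0], -1), fmt='%d', delimiter=',')",
    "b = (np.arange(72, dtype=np.float32) + 0.5).reshape(2, 6, 6)",
    sprintf("tifffile.imwrite(%s, b)", shQuote(theirs))
  ), script)
  status <- system2(py, c(script, out_csv), stdout = TRUE, stderr = TRUE)

  # our file, read by tifffile: page i is z-slice i, rows are y, cols are x
  their_view <- as.matrix(read.csv(out_csv, header = FALSE))
  expect_equal(dim(their_view), c(3L, 24L))
  for (iz in 1:3)
    expect_equal(matrix(as.numeric(their_view[iz, ]), 6, 4, byrow = TRUE),
                 stack$voxels[iz, , ], ignore_attr = TRUE)

  # tifffile's float32 file, read by us
  back <- read_stack(theirs, spacing = c(30, 10, 10))
  expect_equal(back$voxels,
               array(as.numeric(aperm(array(0:71 + 0.5, dim = c(6, 6, 2)), c(3, 2, 1))),
                     dim = c(2, 6, 6)),
               tolerance = 1e-7)
})

test_that("plate maps round trip through CSV, including fractional maps", {
  ones <- plate_map(matrix(1, 8, 12))
  path <- withr::local_tempfile(fileext = ".csv")
  write_plate_map(ones, path)
  expect_true(all(read_plate_map(path)$values == 1))

  frac <- plate_map(matrix(round(runif(96), 6), 8, 12))
  write_plate_map(frac, path)
  expect_equal(read_plate_map(path)$values, frac$values, tolerance = 1e-12)
})

test_that("malformed plate maps are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  ok <- plate_map(matrix(0, 8, 12))
  write_plate_map(ok, path)
  lines <- readLines(path)
  writeLines(lines[-9], path)  # drop row H
  expect_error(read_plate_map(path), "A-H")
  writeLines(c(lines[1], lines[c(3, 2, 4:9)]), path)  # rows out of order
  expect_error(read_plate_map(path), "A-H")
  expect_error(plate_map(matrix(2, 8, 12)), "\\[0, 1\\]")
  expect_error(plate_map(matrix(0, 7, 12)), "8 x 12")
})

test_that("stack and plate-map input validation catches contract violations", {
  expect_error(read_stack("no/such/file.tif", c(30, 10, 10)), "not found")
  expect_error(image_stack(array(0, c(2, 2, 2)), spacing = c(0, 10, 10)), "positive")
  # pages of unequal size: error, not silent cropping
  p1 <- withr::local_tempfile(fileext = ".tif")
  p2 <- withr::local_tempfile(fileext = ".tif")
  write_stack(image_stack(array(1, c(1, 4, 4)), c(30, 10, 10)), p1, "uint8")
  write_stack(image_stack(array(1, c(1, 5, 5)), c(30, 10, 10)), p2, "uint8")
  combined <- withr::local_tempfile(fileext = ".tif")
  # splice the raw IFD chain of two unequal pages into one file
  b1 <- readBin(p1, "raw", file.size(p1)); b2 <- readBin(p2, "raw", file.size(p2))
  n1 <- length(b1)
  patch32 <- function(raw, at, value) {
    raw[at:(at + 3)] <- writeBin(as.integer(value), raw(), size = 4L, endian = "little")
    raw
  }
  # point the first page's next-IFD pointer at the relocated second IFD:
  # bytes of the second file at old offset k land at n1 + (k - 8)
  n_tags <- readBin(b1[9:10], "integer", 1, 2, endian = "little")
  next_ptr_at <- 8 + 2 + n_tags * 12 + 1
  b1 <- patch32(b1, next_ptr_at, n1)
  b2p <- b2
  n_tags2 <- readBin(b2[9:10], "integer", 1, 2, endian = "little")
  for (t in seq_len(n_tags2)) {
    at <- 10 + (t - 1) * 12 + 1
    code <- readBin(b2[at:(at + 1)], "integer", 1, 2, endian = "little")
    if (code == 273) {
      old <- readBin(b2[(at + 8):(at + 11)], "integer", 1, 4, endian = "little")
      b2p <- patch32(b2p, at + 8, old + n1 - 8)
    }
  }
  writeBin(c(b1, b2p[-(1:8)]), combined)
  expect_error(tiff_pages <- read_stack(combined, c(30, 10, 10)), "unequal")
})
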