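test_that("map round-trips through the CCP4 writer and reader", {
  set.seed(42)
  data <- float32(array(rnorm(16^3), c(16, 16, 16)))
  m <- density_map(data, voxel_size = c(1.25, 1.25, 1.25),
                   origin = c(-4, 2.5, 0.75))
  f <- withr::local_tempfile(fileext = ".mrc")
  write_ccp4(m, f)
  m2 <- read_ccp4(f)
  expect_identical(m2$data, data)
  expect_identical(m2$voxel_size, m$voxel_size)
  expect_identical(m2$origin, m$origin)
  expect_equal(m2$origin_source, "explicit")

  # a second round trip is the identity even for unsnapped inputs
  set.seed(7)
  raw <- density_map(array(rnorm(8^3), c(8, 8, 8)),
                     voxel_size = c(1.0, 1.1, 1.2))
  f1 <- withr::local_tempfile(fileext = ".mrc")
  write_ccp4(raw, f1)
  once <- read_ccp4(f1)
  expect_equal(once$voxel_size, raw$voxel_size, tolerance = 1e-6)
  expect_equal(once$data, raw$data, tolerance = 1e-6)
  f2 <- withr::local_tempfile(fileext = ".mrc")
  write_ccp4(once, f2)
  twice <- read_ccp4(f2)
  expect_identical(twice$data, once$data)
  expect_identical(twice$voxel_size, once$voxel_size)
})

test_that("permuted-axis files canonicalize to the same volume", {
  set.seed(11)
  m <- density_map(array(rnorm(6 * 7 * 8), c(6, 7, 8)))
  perms <- list(c(3, 2, 1), c(2, 3, 1), c(3, 1, 2))
  f0 <- withr::local_tempfile(fileext = ".mrc")
  write_ccp4(m, f0)
  ref <- read_ccp4(f0)
  for (p in perms) {
    f <- withr::local_tempfile(fileext = ".mrc")
    write_ccp4(m, f, axis_order = p)
    got <- read_ccp4(f)
    expect_identical(got$data, ref$data)
    expect_identical(got$axis_order, as.integer(p))
  }
})

test_that("integer storage modes 0 and 1 are read as floating point", {
  set.seed(3)
  for (spec in list(list(mode = 0L, vals = sample(-100:100, 4^3, TRUE)),
                    list(mode = 1L, vals = sample(-3000:3000, 4^3, TRUE)))) {
    f <- withr::local_tempfile(fileext = ".mrc")
    write_integer_mode_map(f, spec$vals, c(4, 4, 4), spec$mode)
    m <- read_ccp4(f)
    expect_type(m$data, "double")
    expect_identical(as.vector(m$data), as.double(spec$vals))
  }
})

test_that("malformed files raise distinct named errors", {
  f <- withr::local_tempfile(fileext = ".mrc")
  writeBin(raw(100), f)
  expect_error(read_ccp4(f), "truncated header")

  m <- density_map(array(0, c(4, 4, 4)))
  write_ccp4(m, f)
  raw <- readBin(f, "raw", file.info(f)$size)
  bad <- raw
  bad[13:16] <- writeBin(5L, raw(), size = 4, endian = "little")
  writeBin(bad, f)
  expect_error(read_ccp4(f), "unsupported mode.*5")

  bad <- raw
  bad[65:68] <- writeBin(2L, raw(), size = 4, endian = "little") # MAPC = MAPR
  bad[13:16] <- writeBin(2L, raw(), size = 4, endian = "little")
  writeBin(bad, f)
  expect_error(read_ccp4(f), "MAPC/MAPR/MAPS")

  writeBin(raw[1:1200], f)
  expect_error(read_ccp4(f), "truncated data")
})

test_that("header/data statistic disagreement warns and the data win", {
  m <- density_map(array(0, c(8, 8, 8)))
  f <- withr::local_tempfile(fileext = ".mrc")
  write_ccp4(m, f)
  patch_header_float(f, 22, 1.0)  # claim mean 1.0 over all-zero data
  expect_warning(m2 <- read_ccp4(f), "header statistics disagree")
  expect_identical(m2$header_stats$mean, 0)
  expect_identical(m2$header_stats$rms, 0)
})

test_that("recompute_stats follows its definitions", {
  const <- density_map(array(3.5, c(4, 4, 4)))
  s <- recompute_stats(const)
  expect_equal(unlist(s), c(min = 3.5, max = 3.5, mean = 3.5, rms = 0))

  pm <- density_map(array(rep(c(-1, 1), 32), c(4, 4, 4)))
  s <- recompute_stats(pm)
  expect_equal(s$mean, 0)
  expect_equal(s$rms, 1)

  set.seed(9)
  n <- 32^3
  z <- density_map(array(rnorm(n), c(32, 32, 32)))
  s <- recompute_stats(z)
  expect_lt(abs(s$mean), 4 / sqrt(n))
  expect_lt(abs(s$rms - 1), 4 / sqrt(n))

  # invariant under axis permutation of the volume
  set.seed(10)
  x <- array(rnorm(5 * 6 * 7), c(5, 6, 7))
  expect_equal(recompute_stats(density_map(x)),
               recompute_stats(density_map(aperm(x, c(3, 1, 2)))))
})

test_that("invalid maps are rejected at construction and write time", {
  expect_error(density_map(array(0, c(2, 2, 2)), voxel_size = c(1, -1, 1)),
               "positive")
  expect_error(density_map(matrix(0, 2, 2)), "3D")
  bad <- density_map(array(0, c(2, 2, 2)))
  bad$data[1] <- NaN
  f <- withr::local_tempfile(fileext = ".mrc")
  expect_error(write_ccp4(bad, f), "non-finite")
  write_ccp4(bad, f, sanitize = TRUE)
  expect_identical(read_ccp4(f)$data, array(0, c(2, 2, 2)))
})
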