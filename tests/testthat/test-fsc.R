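test_that("self-correlation is 1 in every shell", {
  m <- centered_helix_map(dim = 24)
  curve <- compute_fsc(m, m)
  expect_true(all(abs(curve$correlations - 1) < 1e-6, na.rm = TRUE))
  expect_true(all(diff(curve$frequencies) > 0))
  expect_true(all(curve$frequencies <= curve$nyquist + 1e-12))
  expect_true(all(curve$shell_counts >= 1))
})

test_that("FSC is symmetric and invariant under positive scaling", {
  set.seed(21)
  a <- white_noise_map(16, seed = 1)
  b <- white_noise_map(16, seed = 2)
  ab <- compute_fsc(a, b)
  ba <- compute_fsc(b, a)
  expect_identical(ab$correlations, ba$correlations)

  a3 <- density_map(a$data * 3.7, voxel_size = a$voxel_size)
  b5 <- density_map(b$data * 0.02, voxel_size = b$voxel_size)
  scaled <- compute_fsc(a3, b5)
  expect_equal(scaled$correlations, ab$correlations, tolerance = 1e-12)
})

test_that("FFT-based FSC matches the direct-summation DFT oracle", {
  for (n in c(8L, 12L)) {
    set.seed(100 + n)
    a <- density_map(array(rnorm(n^3), rep(n, 3)))
    sig <- centered_helix_map(n_res = if (n == 8L) 4L else 6L, dim = n,
                              sigma = 1.2)
    set.seed(200 + n)
    b <- density_map(sig$data + array(rnorm(n^3), rep(n, 3)))
    curve <- compute_fsc(a, b)
    oracle <- dft_fsc(a, b)
    expect_equal(curve$correlations, oracle, tolerance = 1e-9)
  }
})

test_that("independent noise maps give null FSC within counting bounds", {
  inside <- 0L
  total <- 0L
  for (seed in 1:20) {
    a <- white_noise_map(32, seed = 1000 + seed)
    b <- white_noise_map(32, seed = 5000 + seed)
    curve <- compute_fsc(a, b)
    keep <- curve$frequencies > 0
    bound <- 3 / sqrt(curve$shell_counts[keep])
    inside <- inside + sum(abs(curve$correlations[keep]) <= bound)
    total <- total + sum(keep)
  }
  expect_gte(inside / total, 0.95)
})

test_that("grid, voxel and degenerate input mismatches are distinct errors", {
  a <- white_noise_map(8, seed = 1)
  b <- white_noise_map(10, seed = 1)
  expect_error(compute_fsc(a, b), "grid mismatch")
  c <- white_noise_map(8, voxel_size = 1.2, seed = 1)
  expect_error(compute_fsc(a, c), "voxel-size mismatch")
  aniso <- white_noise_map(8, voxel_size = c(1, 1, 1.5), seed = 1)
  expect_error(compute_fsc(aniso, aniso), "anisotropic")
  z <- density_map(array(0, c(8, 8, 8)))
  expect_error(compute_fsc(a, z), "all-zero")
})

test_that("resolution crossings are interpolated between shell centers", {
  f <- c(0, 0.1, 0.2, 0.3, 0.4)
  curve <- structure(list(frequencies = f,
                          correlations = c(1, 1, 1, 0.5 + 1e-9, 0.1),
                          shell_counts = c(1, 10, 40, 90, 160),
                          nyquist = 0.5),
                     class = "fsc_curve")
  est <- estimate_resolution(curve, "fixed-0.5")
  expect_true(est$reached)
  # crossing between shells 4 and 5: 0.3 + (0.5-0.5)/(0.5-0.1)*0.1 ~ 0.3
  expect_equal(est$crossing_frequency, 0.3, tolerance = 1e-6)
  expect_equal(est$resolution, 1 / est$crossing_frequency)

  est143 <- estimate_resolution(curve, "0.143")
  expect_gt(est143$crossing_frequency, 0.3)
  expect_lt(est143$crossing_frequency, 0.4)
  # hand-computed interpolation between (0.3, 0.5) and (0.4, 0.1)
  expect_equal(est143$crossing_frequency, 0.3 + 0.1 * (0.5 - 0.143) / 0.4,
               tolerance = 1e-9)

  # counts large enough that every criterion's threshold stays below 1
  flat <- structure(list(frequencies = f, correlations = rep(1, 5),
                         shell_counts = c(1, 200, 400, 800, 1600),
                         nyquist = 0.5),
                    class = "fsc_curve")
  for (cr in c("fixed-0.5", "fixed-0.143", "half-bit", "three-sigma")) {
    e <- estimate_resolution(flat, cr)
    expect_false(e$reached)
    expect_true(is.na(e$resolution))
    expect_equal(e$resolution_bound, 2)
  }
})

test_that("count-dependent thresholds follow their formulas", {
  n <- c(12, 100, 1000)
  expect_equal(fsc_threshold("half-bit", n),
               (0.2071 + 1.9102 / sqrt(n)) / (1.2071 + 0.9102 / sqrt(n)))
  expect_equal(fsc_threshold("three-sigma", n), 3 / sqrt(n / 2))
  expect_error(estimate_resolution(
    structure(list(frequencies = c(0, 0.1), correlations = c(1, 1),
                   shell_counts = c(NA_real_, NA_real_), nyquist = 0.5),
              class = "fsc_curve"), "half-bit"),
    "voxel counts")
})

test_that("FSC XML round-trips at six significant digits", {
  m <- centered_helix_map(dim = 16)
  noisy <- half_map_pair(m, 0.3, seed = 8)
  curve <- compute_fsc(noisy$a, noisy$b)
  f <- withr::local_tempfile(fileext = ".xml")
  write_fsc_xml(curve, f)
  back <- read_fsc_xml(f)
  expect_length(back$frequencies, length(curve$frequencies))
  expect_equal(back$frequencies, curve$frequencies, tolerance = 1e-6)
  expect_equal(back$correlations, curve$correlations, tolerance = 1e-6)
  expect_true(all(diff(back$frequencies) > 0))

  doc <- xml2::read_xml(f)
  expect_equal(xml2::xml_name(doc), "fsc")
  expect_length(xml2::xml_find_all(doc, "./coordinate"),
                length(curve$frequencies))
})

test_that("malformed FSC XML is rejected with specific errors", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines("<fsc title='t'></fsc>", f)
  expect_error(read_fsc_xml(f), "no coordinates")

  writeLines(paste0("<fsc><coordinate><x>0.2</x><y>1</y></coordinate>",
                    "<coordinate><x>0.1</x><y>1</y></coordinate></fsc>"), f)
  expect_error(read_fsc_xml(f), "non-monotone")

  writeLines("<fsc><coordinate><x>0.1</x></coordinate></fsc>", f)
  expect_error(read_fsc_xml(f), "missing x or y")
})
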