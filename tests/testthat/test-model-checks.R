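test_that("PDB and mmCIF fixtures parse to the same model", {
  fp <- write_ca_pdb(withr::local_tempfile(fileext = ".pdb"))
  fc <- write_ca_cif(withr::local_tempfile(fileext = ".cif"))
  mp <- parse_model(fp)
  mc <- parse_model(fc)
  expect_equal(nrow(mp$atoms), 3L)
  expect_equal(unname(mp$chain_types), "protein")
  for (col in c("chain", "resno", "resid", "elety", "x", "y", "z"))
    expect_equal(mp$atoms[[col]], mc$atoms[[col]])
  expect_error(parse_model("does-not-exist.pdb"), "not found")
})

test_that("alternate locations resolve to the highest occupancy", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "CA", "A", "ALA", "A", 1, 0, 0, 0, occ = 0.6),
    pdb_line(2, "CA", "B", "ALA", "A", 1, 5, 0, 0, occ = 0.4),
    pdb_line(3, "CA", " ", "ALA", "A", 2, 3.8, 0, 0),
    "END"), f)
  m <- parse_model(f)
  expect_equal(nrow(m$atoms), 2L)
  kept <- m$atoms[m$atoms$resno == 1, ]
  expect_equal(kept$x, 0)
  expect_equal(kept$o, 0.6)
})

test_that("trace classification follows the one-atom-per-residue rule", {
  h <- helix_trace(5)
  tr <- classify_trace(h)
  expect_equal(tr$trace_kind, "calpha-only")
  expect_true(tr$is_trace)

  p <- p_trace(10, spacing = 5.9)
  expect_equal(classify_trace(p)$trace_kind, "p-only")

  # full-atom-ish chain: residues with more than one atom are not a trace
  full <- atom_model(data.frame(
    chain = "A", resno = rep(1:3, each = 2), resid = "GLY",
    elety = rep(c("N", "CA"), 3),
    x = seq(0, 2.5, length.out = 6), y = 0, z = 0))
  expect_equal(classify_trace(full)$trace_kind, "none")

  # mixed chain (one residue full-atom) is not a trace either
  mixed <- atom_model(data.frame(
    chain = "A", resno = c(1, 2, 2, 3), resid = "GLY",
    elety = c("CA", "CA", "CB", "CA"),
    x = c(0, 3.8, 4.2, 7.6), y = 0, z = 0))
  expect_equal(classify_trace(mixed)$trace_kind, "none")
})

test_that("CA-CA outliers need to escape both the cis and trans windows", {
  ref <- reference_distributions(caca_cis = c(2.9, 0.05),
                                 caca_trans = c(3.8, 0.02))
  trans_mean_chain <- function(d) atom_model(data.frame(
    chain = "A", resno = 1:2, resid = "ALA", elety = "CA",
    x = c(0, d), y = 0, z = 0))

  expect_equal(sum(caca_distance_outliers(helix_trace(10), ref)$outlier), 0L)

  all_trans <- atom_model(data.frame(
    chain = "A", resno = 1:5, resid = "ALA", elety = "CA",
    x = cumsum(c(0, rep(3.8, 4))), y = 0, z = 0))
  expect_equal(sum(caca_distance_outliers(all_trans, ref)$outlier), 0L)

  # one bond at trans mean + 3.1 sigma (far outside the cis window too)
  res <- caca_distance_outliers(trans_mean_chain(3.8 + 3.1 * 0.02), ref)
  expect_equal(sum(res$outlier), 1L)
  expect_equal(res$nearest_class, "trans")
  expect_equal(res$deviation_sigma, 3.1, tolerance = 1e-9)

  # at the cis mean: inside the cis window, hence acceptable
  res <- caca_distance_outliers(trans_mean_chain(2.9), ref)
  expect_equal(sum(res$outlier), 0L)

  # strictness: exactly 3 sigma from the trans mean is not flagged
  # (dyadic reference values so the z-score is exact in floating point)
  ref_dyadic <- reference_distributions(caca_cis = c(2.0, 0.125),
                                        caca_trans = c(3.5, 0.25))
  res <- caca_distance_outliers(trans_mean_chain(4.25), ref_dyadic)
  expect_equal(sum(res$outlier), 0L)
  res <- caca_distance_outliers(trans_mean_chain(4.3125), ref_dyadic)
  expect_equal(sum(res$outlier), 1L)

  # numbering gap: bond skipped, not flagged
  gap <- atom_model(data.frame(
    chain = "A", resno = c(1, 2, 5, 6), resid = "ALA", elety = "CA",
    x = c(0, 3.8, 30, 33.8), y = 0, z = 0))
  res <- caca_distance_outliers(gap, ref)
  expect_equal(nrow(res), 2L)
  expect_equal(sum(res$outlier), 0L)

  # a single-residue chain yields empty findings, not an error
  one <- atom_model(data.frame(chain = "A", resno = 1, resid = "ALA",
                               elety = "CA", x = 0, y = 0, z = 0))
  expect_equal(nrow(caca_distance_outliers(one, ref)), 0L)
})

test_that("P-P outliers use strict 4.4/8.0 A bounds", {
  res <- pp_distance_outliers(p_trace(spacing = c(4.3, 6.0, 8.1)))
  expect_equal(sum(res$outlier), 2L)
  expect_equal(res$reason[res$outlier], c("short", "long"))

  boundary <- pp_distance_outliers(p_trace(spacing = c(4.4, 8.0)))
  expect_equal(sum(boundary$outlier), 0L)

  expect_equal(sum(pp_distance_outliers(p_trace(10, 5.9))$outlier), 0L)
  expect_equal(nrow(pp_distance_outliers(p_trace(2, 5.0))), 1L)

  # findings recomputable from the model to high precision
  m <- p_trace(spacing = c(4.3, 6.0, 8.1))
  res <- pp_distance_outliers(m)
  a <- m$atoms
  d_direct <- sqrt(diff(a$x)^2 + diff(a$y)^2 + diff(a$z)^2)
  expect_equal(res$distance, d_direct, tolerance = 1e-9)
})

test_that("pseudo-Ramachandran scoring is self-consistent and windowed", {
  helix <- helix_trace(12)
  ref <- default_reference_distributions()
  res <- pseudo_ramachandran(helix, ref)
  expect_equal(nrow(res), 12L - 3L)
  expect_equal(sum(res$outlier), 0L)
  # ideal helix: all interior (theta, eta) pairs identical
  expect_lt(diff(range(res$theta)), 1e-9)
  expect_lt(diff(range(res$eta)), 1e-9)

  # adversarial grid: uniform everywhere except zero on the helical bins
  g <- ref$rama
  adv <- g
  ti <- emval:::rama_bin_theta(res$theta[1], g$bin_width, nrow(g$freq))
  ei <- emval:::rama_bin_eta(res$eta[1], g$bin_width, ncol(g$freq))
  adv$freq[] <- 1 / length(adv$freq)
  adv$freq[ti, ei] <- 0
  adv$freq <- adv$freq / sum(adv$freq)
  adv$cutoff <- 1e-12
  advref <- reference_distributions(rama = adv)
  res2 <- pseudo_ramachandran(helix, advref)
  expect_equal(sum(res2$outlier), nrow(res2))

  # four residues -> exactly one scored residue
  expect_equal(nrow(pseudo_ramachandran(helix_trace(4), ref)), 1L)

  # missing grid is an explicit error
  noref <- reference_distributions()
  expect_error(pseudo_ramachandran(helix, noref), "reference required")
})

test_that("grid-based clash detection equals the all-pairs oracle", {
  set.seed(99)
  n <- 200
  atoms <- data.frame(
    chain = sample(c("A", "B"), n, TRUE),
    resno = sample(1:40, n, TRUE), resid = "ALA",
    elety = sample(c("CA", "CB", "N", "O"), n, TRUE),
    x = runif(n, 0, 18), y = runif(n, 0, 18), z = runif(n, 0, 18))
  atoms$elesy <- substr(atoms$elety, 1, 1)
  m <- atom_model(atoms)
  got <- close_contacts(m)
  oracle <- brute_clashes(m)
  expect_equal(nrow(got), nrow(oracle))
  expect_equal(got$i, oracle$i)
  expect_equal(got$j, oracle$j)
  expect_equal(got$distance, oracle$distance, tolerance = 1e-9)
})

test_that("clash arithmetic and exclusions behave as documented", {
  two_c <- function(d, resno2 = 10) atom_model(data.frame(
    chain = "A", resno = c(1, resno2), resid = "ALA",
    elety = c("CB", "CB"), elesy = "C", x = c(0, d), y = 0, z = 0))
  expect_equal(nrow(close_contacts(two_c(4.0))), 0L)   # 4.0 > 3.0
  res <- close_contacts(two_c(2.5))
  expect_equal(nrow(res), 1L)
  expect_equal(res$overlap, 0.9, tolerance = 1e-9)

  # unknown element: warn and skip
  odd <- atom_model(data.frame(
    chain = "A", resno = c(1, 10), resid = "LIG", elety = c("XX", "CB"),
    elesy = c("XX", "C"), x = c(0, 1), y = 0, z = 0))
  expect_warning(res <- close_contacts(odd), "XX")
  expect_equal(nrow(res), 0L)
})

test_that("atom inclusion interpolates density and honors the origin", {
  set.seed(55)
  m <- density_map(array(runif(8^3), c(8, 8, 8)),
                   voxel_size = c(1.5, 1.5, 1.5), origin = c(10, -5, 3))
  # atoms exactly at voxel centers: interpolation equals the voxel value
  idx <- cbind(c(1, 3, 5, 8), c(2, 4, 6, 8), c(1, 5, 7, 8))
  pos <- sweep(sweep(idx - 1, 2, m$voxel_size, "*"), 2, m$origin, "+")
  model <- atom_model(data.frame(
    chain = "A", resno = seq_len(nrow(idx)), resid = "ALA", elety = "CA",
    x = pos[, 1], y = pos[, 2], z = pos[, 3]))
  inc <- atom_inclusion(model, m, contour = 0.5)
  expect_equal(inc$atoms$density, m$data[idx], tolerance = 1e-12)
  expect_equal(inc$fraction, mean(m$data[idx] >= 0.5))

  expect_equal(atom_inclusion(model, m, contour = min(m$data))$fraction, 1)
  expect_equal(atom_inclusion(model, m, contour = max(m$data) + 1)$fraction, 0)

  # nearest-voxel option agrees at voxel centers
  expect_equal(atom_inclusion(model, m, 0.5, method = "nearest")$atoms$density,
               inc$atoms$density, tolerance = 1e-12)

  # atom outside the grid counts as excluded
  out_model <- atom_model(data.frame(
    chain = "A", resno = 1:2, resid = "ALA", elety = "CA",
    x = c(10, 1000), y = c(-5, 0), z = c(3, 0)))
  inc2 <- atom_inclusion(out_model, m, contour = min(m$data))
  expect_equal(inc2$atoms$inside, c(TRUE, FALSE))
  expect_equal(inc2$fraction, 0.5)

  expect_error(atom_inclusion(atom_model(data.frame(
    chain = character(), resno = integer(), resid = character(),
    elety = character(), x = numeric(), y = numeric(), z = numeric())),
    m, 0), "no atoms")

  # inclusion is non-increasing in the contour level
  set.seed(66)
  fr <- vapply(seq(0, 1, length.out = 11),
               function(ct) atom_inclusion(model, m, ct)$fraction, numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("findings are invariant under rigid translation and chain order", {
  helix <- helix_trace(10)
  ref <- default_reference_distributions()
  shift <- c(12.3, -4.5, 6.7)
  a <- helix$atoms
  moved <- atom_model(transform(a, x = x + shift[1], y = y + shift[2],
                                z = z + shift[3]))
  expect_equal(caca_distance_outliers(moved, ref)$distance,
               caca_distance_outliers(helix, ref)$distance, tolerance = 1e-9)
  r1 <- pseudo_ramachandran(moved, ref)
  r0 <- pseudo_ramachandran(helix, ref)
  expect_equal(r1$theta, r0$theta, tolerance = 1e-9)
  expect_equal(r1$eta, r0$eta, tolerance = 1e-9)

  # translating model and map origin together preserves inclusion
  m <- centered_helix_map(n_res = 10, dim = 24)
  hm <- helix_trace(10)$atoms
  ctr <- (24 - 1) / 2
  hm$x <- hm$x - mean(hm$x) + ctr
  hm$y <- hm$y - mean(hm$y) + ctr
  hm$z <- hm$z - mean(hm$z) + ctr
  model0 <- atom_model(hm)
  inc0 <- atom_inclusion(model0, m, 0.2)
  m2 <- density_map(m$data, voxel_size = m$voxel_size,
                    origin = m$origin + shift)
  model2 <- atom_model(transform(hm, x = x + shift[1], y = y + shift[2],
                                 z = z + shift[3]))
  inc2 <- atom_inclusion(model2, m2, 0.2)
  expect_equal(inc2$fraction, inc0$fraction)
  expect_equal(inc2$atoms$density, inc0$atoms$density, tolerance = 1e-9)

  # chain order permutation leaves per-chain findings unchanged
  two <- rbind(transform(helix_trace(8, chain = "B")$atoms, x = x + 30),
               p_trace(6, spacing = c(4.3, 6, 6, 6, 8.1), chain = "A")$atoms)
  model_ab <- atom_model(two)
  res <- pp_distance_outliers(model_ab)
  expect_equal(sum(res$outlier), 2L)
})
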