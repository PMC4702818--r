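# Fixtures and independent oracles used across the suite.

# helix-derived Gaussian-atom map centered in its grid; by default the
# helix length is chosen to fit the box with margin
centered_helix_map <- function(n_res = NULL, dim = 32, sigma = 1.5,
                               voxel = 1) {
  if (is.null(n_res))
    n_res <- max(4L, min(12L, floor((dim - 1) * voxel * 0.7 / 1.5)))
  model <- helix_trace(n_res)
  a <- model$atoms
  ctr <- (dim - 1) * voxel / 2
  a$x <- a$x - mean(a$x) + ctr
  a$y <- a$y - mean(a$y) + ctr
  a$z <- a$z - mean(a$z) + ctr
  gaussian_atom_map(atom_model(a), dim = dim, voxel_size = voxel,
                    sigma = sigma)
}

# Brute-force O(N^2) discrete Fourier transform, written independently of
# stats::fft: direct summation over all voxels for every Fourier voxel.
dft3 <- function(x) {
  d <- dim(x)
  i1 <- array(rep(0:(d[1] - 1), times = d[2] * d[3]), d)
  i2 <- array(rep(rep(0:(d[2] - 1), each = d[1]), times = d[3]), d)
  i3 <- array(rep(0:(d[3] - 1), each = d[1] * d[2]), d)
  F <- array(0i, d)
  for (k1 in 0:(d[1] - 1)) for (k2 in 0:(d[2] - 1)) for (k3 in 0:(d[3] - 1))
    F[k1 + 1, k2 + 1, k3 + 1] <-
      sum(x * exp(-2i * pi * (k1 * i1 / d[1] + k2 * i2 / d[2] +
                                k3 * i3 / d[3])))
  F
}

# FSC by direct DFT summation over shells (independent accumulation path)
dft_fsc <- function(a, b) {
  d <- dim(a$data)
  v <- a$voxel_size
  Fa <- dft3(a$data)
  Fb <- dft3(b$data)
  fr <- function(ax) {
    k <- 0:(d[ax] - 1)
    kk <- ifelse(k > d[ax] %/% 2, k - d[ax], k)
    kk / (d[ax] * v[ax])
  }
  f1 <- fr(1); f2 <- fr(2); f3 <- fr(3)
  num <- c(); pa <- c(); pb <- c()
  ds <- 1 / max(d * v)
  nbin <- floor((1 / (2 * mean(v))) / ds + 1e-9) + 1
  num <- pa <- pb <- numeric(nbin)
  for (k1 in seq_len(d[1])) for (k2 in seq_len(d[2])) for (k3 in seq_len(d[3])) {
    r <- sqrt(f1[k1]^2 + f2[k2]^2 + f3[k3]^2)
    bin <- round(r / ds) + 1
    if (bin > nbin) next
    num[bin] <- num[bin] + Re(Fa[k1, k2, k3] * Conj(Fb[k1, k2, k3]))
    pa[bin] <- pa[bin] + Mod(Fa[k1, k2, k3])^2
    pb[bin] <- pb[bin] + Mod(Fb[k1, k2, k3])^2
  }
  num / sqrt(pa * pb)
}

# All-pairs clash oracle with the same exclusion semantics, written
# independently of the grid implementation.
brute_clashes <- function(model, vdw = default_vdw_radii(), tol = 0.4) {
  a <- model$atoms
  r <- unname(vdw[a$elesy])
  bb <- c("N", "CA", "C", "O", "OXT", "P", "OP1", "OP2", "OP3",
          "O5'", "C5'", "C4'", "C3'", "O3'", "O4'", "C2'", "C1'", "O2'")
  out <- list()
  n <- nrow(a)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (is.na(r[i]) || is.na(r[j])) next
    if (a$chain[i] == a$chain[j]) {
      if (a$resno[i] == a$resno[j]) next
      if (abs(a$resno[i] - a$resno[j]) == 1 &&
          a$elety[i] %in% bb && a$elety[j] %in% bb) next
    }
    d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                (a$z[i] - a$z[j])^2)
    if (d < r[i] + r[j] - tol)
      out[[length(out) + 1]] <- c(i, j, d)
  }
  if (length(out) == 0)
    return(data.frame(i = integer(), j = integer(), distance = numeric()))
  m <- do.call(rbind, out)
  data.frame(i = m[, 1], j = m[, 2], distance = m[, 3])
}

# fixed-width PDB ATOM line
pdb_line <- function(serial, name, alt, resname, chain, resno, x, y, z,
                     occ = 1, b = 0, element = "C") {
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, paste0(" ", name), alt, resname, chain, resno,
          x, y, z, occ, b, element)
}

write_ca_pdb <- function(path) {
  writeLines(c(
    pdb_line(1, "CA", " ", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", " ", "ALA", "A", 2, 3.8, 0, 0),
    pdb_line(3, "CA", " ", "ALA", "A", 3, 7.6, 0, 0),
    "END"), path)
  path
}

write_ca_cif <- function(path) {
  writeLines(c(
    "data_ca3", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 C CA . ALA A 1 1 ? 0.000 0.000 0.000 1.00 10.00 1 ALA A CA 1",
    "ATOM 2 C CA . ALA A 1 2 ? 3.800 0.000 0.000 1.00 10.00 2 ALA A CA 1",
    "ATOM 3 C CA . ALA A 1 3 ? 7.600 0.000 0.000 1.00 10.00 3 ALA A CA 1",
    "#"), path)
  path
}

# rewrite a map file as mode 0 (int8) or mode 1 (int16), keeping the header
write_integer_mode_map <- function(path, values, dims, mode) {
  stopifnot(mode %in% c(0L, 1L))
  m <- density_map(array(as.double(values), dims))
  write_ccp4(m, path)
  hdr <- readBin(path, "raw", 1024)
  hdr[13:16] <- writeBin(as.integer(mode), raw(), size = 4,
                         endian = "little")
  con <- file(path, "wb")
  writeBin(hdr, con)
  writeBin(as.integer(values), con, size = if (mode == 0L) 1L else 2L,
           endian = "little")
  close(con)
  path
}

# patch a float word (1-based header word index) in a map file
patch_header_float <- function(path, word, value) {
  raw <- readBin(path, "raw", file.info(path)$size)
  raw[(4 * (word - 1) + 1):(4 * word)] <-
    writeBin(as.numeric(value), raw(), size = 4, endian = "little")
  writeBin(raw, path)
  path
}
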