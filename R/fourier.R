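# Shared reciprocal-space shell machinery for FSC and the rotationally
# averaged power spectrum.
#
# Shells are one reciprocal-grid step wide: bin index = round(|s| / ds) with
# ds = 1/(N * voxel_size) taken from the finest-sampled axis, shell centers
# at i * ds. Bins whose centers exceed the Nyquist frequency 1/(2 * voxel)
# (corner voxels of the Fourier cube) are dropped. Conjugate-symmetric
# voxels of the real-input transform are counted once in `n_unique`:
# self-conjugate voxels (index 0 or N/2 on every axis) count 1, every
# Hermitian pair counts 1.

fourier_shells <- function(dims, voxel_size) {
  dims <- as.integer(dims)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  freq_axis <- function(a) {
    n <- dims[a]
    k <- 0:(n - 1L)
    kk <- ifelse(k > n %/% 2, k - n, k)
    kk / (n * voxel_size[a])
  }
  f1 <- freq_axis(1L); f2 <- freq_axis(2L); f3 <- freq_axis(3L)
  r2 <- outer(f1^2, f2^2, "+")
  r <- sqrt(array(r2, dims) +
              rep(f3^2, each = dims[1L] * dims[2L]))
  ds <- 1 / max(dims * voxel_size)
  nyquist <- 1 / (2 * mean(voxel_size))
  bin <- as.integer(round(r / ds))
  nbin <- as.integer(floor(nyquist / ds + 1e-9)) + 1L  # bins 0..nbin-1
  keep <- bin < nbin

  self_axis <- function(a) {
    n <- dims[a]
    k <- 0:(n - 1L)
    (n - k) %% n == k
  }
  s1 <- self_axis(1L); s2 <- self_axis(2L); s3 <- self_axis(3L)
  self <- array(outer(s1, s2, "&"), dims) &
    rep(s3, each = dims[1L] * dims[2L])

  n_full <- tabulate(bin[keep] + 1L, nbins = nbin)
  n_self <- tabulate(bin[keep & self] + 1L, nbins = nbin)
  list(bin = bin, keep = keep, freq = (0:(nbin - 1L)) * ds,
       n_full = n_full, n_unique = (n_full + n_self) / 2,
       ds = ds, nyquist = nyquist, nbin = nbin)
}

# sum a per-voxel quantity over shells; returns a length-nbin vector
shell_sums <- function(v, shells) {
  out <- numeric(shells$nbin)
  t <- rowsum(v[shells$keep], shells$bin[shells$keep])
  out[as.integer(rownames(t)) + 1L] <- t
  out
}

# common precondition for Fourier-space modules
check_cubic_voxels <- function(map, rel_tol = 1e-3) {
  v <- map$voxel_size
  if (max(v) / min(v) > 1 + rel_tol)
    stop("voxels too anisotropic for shell averaging: voxel sizes (",
         paste(signif(v, 6), collapse = ", "),
         ") A differ by more than a factor ", 1 + rel_tol)
  invisible(TRUE)
}
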