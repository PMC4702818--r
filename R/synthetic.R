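# Seeded synthetic fixtures: Gaussian-atom maps, half-map pairs with a
# designed signal-to-noise profile, noise volumes, and ideal/perturbed
# trace models. All randomness is driven by a single integer seed through
# named sub-streams so that fixtures are bit-reproducible.

# deterministic sub-stream seed below 2^31
stream_seed <- function(seed, stream) {
  ((as.numeric(seed) %% 1000003) * 9973 + stream * 7919) %% 2147483629
}

#' Render a model as a Gaussian-atom density map
#'
#' Each atom contributes a unit-amplitude isotropic Gaussian of width
#' `sigma` centered at its position, sampled at voxel centers; the map
#' origin is honored. Every atom must lie inside the grid bounding box.
#'
#' @param model an [atom_model].
#' @param dim grid dimensions, length-3 integer (a scalar is recycled).
#' @param voxel_size voxel size in Angstrom (length 3 or scalar).
#' @param origin position of the first voxel in Angstrom.
#' @param sigma Gaussian width parameter in Angstrom.
#' @return A [density_map].
#' @export
gaussian_atom_map <- function(model, dim = 32L, voxel_size = 1,
                              origin = c(0, 0, 0), sigma = 1.5) {
  stopifnot(inherits(model, "atom_model"))
  dim <- rep_len(as.integer(dim), 3L)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  ax <- lapply(1:3, function(a) origin[a] + (0:(dim[a] - 1L)) * voxel_size[a])
  pos <- as.matrix(model$atoms[, c("x", "y", "z")])
  for (a in 1:3)
    if (any(pos[, a] < min(ax[[a]]) | pos[, a] > max(ax[[a]])))
      stop("atom outside grid bounding box on axis ", c("x", "y", "z")[a])
  arr <- array(0, dim)
  for (k in seq_len(nrow(pos))) {
    gx <- exp(-(ax[[1]] - pos[k, 1])^2 / (2 * sigma^2))
    gy <- exp(-(ax[[2]] - pos[k, 2])^2 / (2 * sigma^2))
    gz <- exp(-(ax[[3]] - pos[k, 3])^2 / (2 * sigma^2))
    arr <- arr + array(outer(gx, gy), dim) * rep(gz, each = dim[1] * dim[2])
  }
  density_map(arr, voxel_size = voxel_size, origin = origin)
}

#' Seeded white-noise map
#'
#' @param dim grid dimensions (scalar recycled).
#' @param voxel_size voxel size in Angstrom.
#' @param sigma noise standard deviation (map units).
#' @param seed integer seed.
#' @return A [density_map] of i.i.d. Gaussian noise.
#' @export
white_noise_map <- function(dim = 32L, voxel_size = 1, sigma = 1, seed = 1L) {
  dim <- rep_len(as.integer(dim), 3L)
  arr <- with_seed(seed, array(stats::rnorm(prod(dim), sd = sigma), dim))
  density_map(arr, voxel_size = voxel_size)
}

#' Generate an independent half-map pair
#'
#' Returns two maps equal to the signal plus independent seeded white
#' Gaussian noise, emulating reconstructions from independent data halves.
#' The two noise realizations come from separate sub-streams of the one
#' seed. The designed per-shell signal-to-noise ratio is
#' `SNR(s) = P_signal(s) / (Nvox * noise_sigma^2)` with `P_signal` the
#' signal's rotationally averaged power spectrum (see [designed_snr()]);
#' under this model the expected FSC is `SNR / (SNR + 1)` per shell.
#'
#' @param signal a [density_map] holding the noise-free structure signal.
#' @param noise_sigma noise standard deviation per voxel (map units, >= 0).
#' @param seed integer seed.
#' @return A list with elements `a` and `b`, both [density_map]s.
#' @export
half_map_pair <- function(signal, noise_sigma, seed = 1L) {
  stopifnot(inherits(signal, "density_map"), noise_sigma >= 0)
  d <- dim(signal$data)
  mk <- function(stream) {
    noise <- with_seed(stream_seed(seed, stream),
                       array(stats::rnorm(prod(d), sd = noise_sigma), d))
    density_map(signal$data + noise, voxel_size = signal$voxel_size,
                origin = signal$origin)
  }
  list(a = mk(1L), b = mk(2L))
}

#' Designed per-shell SNR and expected FSC of a half-map pair
#'
#' For half-maps built as `signal + white noise(sigma)`, the expected
#' per-shell FSC is `SNR/(SNR+1)` with
#' `SNR(s) = P_signal(s) / (Nvox * sigma^2)` (the unnormalized-FFT white
#' noise power per Fourier voxel is `Nvox * sigma^2`).
#'
#' @param signal the noise-free [density_map].
#' @param noise_sigma noise standard deviation per voxel.
#' @return A list with `frequencies`, `snr`, `expected_fsc` and
#'   `snr1_frequency` (the first frequency where SNR falls through 1,
#'   linearly interpolated; `NA` when SNR never falls below 1).
#' @export
designed_snr <- function(signal, noise_sigma) {
  ps <- rotational_power_spectrum(signal)
  snr <- ps$power / (prod(dim(signal$data)) * noise_sigma^2)
  f <- ps$frequencies
  below <- which(snr < 1)
  snr1 <- if (length(below) == 0L || below[1L] == 1L) NA_real_ else {
    k <- below[1L]
    lg <- log(snr)   # interpolate in log-SNR, crossing at log SNR = 0
    f[k - 1L] + (lg[k - 1L] / (lg[k - 1L] - lg[k])) * (f[k] - f[k - 1L])
  }
  list(frequencies = f, snr = snr, expected_fsc = snr / (snr + 1),
       snr1_frequency = snr1)
}

#' Noise level that places the SNR=1 crossing at a target frequency
#'
#' Solves the designed-SNR relation for `noise_sigma` so that the shell
#' nearest `frequency` has SNR exactly 1.
#'
#' @param signal the noise-free [density_map].
#' @param frequency target SNR=1 spatial frequency (1/A).
#' @return Noise standard deviation (map units).
#' @export
noise_sigma_for_snr1 <- function(signal, frequency) {
  ps <- rotational_power_spectrum(signal)
  k <- which.min(abs(ps$frequencies - frequency))
  sqrt(ps$power[k] / prod(dim(signal$data)))
}

#' Ideal helical C-alpha trace
#'
#' Places one CA atom per residue on a regular helix; all consecutive
#' CA--CA distances are equal by construction to
#' `sqrt(rise^2 + (2 r sin(twist/2))^2)` (see [helix_chord()]). Defaults
#' approximate an ideal alpha-helix.
#'
#' @param n_res number of residues (>= 2).
#' @param rise rise per residue in Angstrom.
#' @param twist twist per residue in degrees.
#' @param radius helix radius in Angstrom.
#' @param chain chain identifier.
#' @return An [atom_model] with one CA atom per residue (residue ALA).
#' @export
helix_trace <- function(n_res, rise = 1.5, twist = 100, radius = 2.3,
                        chain = "A") {
  stopifnot(n_res >= 2L)
  i <- 0:(n_res - 1L)
  t <- i * twist * pi / 180
  atom_model(data.frame(
    chain = chain, resno = i + 1L, resid = "ALA", elety = "CA", elesy = "C",
    x = radius * cos(t), y = radius * sin(t), z = i * rise,
    stringsAsFactors = FALSE))
}

#' Chord length between consecutive residues of a regular helix
#'
#' @param rise rise per residue (A).
#' @param twist twist per residue (degrees).
#' @param radius helix radius (A).
#' @return Consecutive CA--CA distance in Angstrom.
#' @export
helix_chord <- function(rise = 1.5, twist = 100, radius = 2.3)
  sqrt(rise^2 + (2 * radius * sin(twist * pi / 360))^2)

#' Collinear P-only nucleic acid trace
#'
#' P atoms on a line with the given spacing; a per-bond spacing vector
#' produces designed distance patterns for threshold tests.
#'
#' @param n_res number of residues; defaults to `length(spacing) + 1` when
#'   `spacing` is a vector.
#' @param spacing consecutive P--P distance(s) in Angstrom: a scalar
#'   (uniform) or a vector of per-bond spacings.
#' @param chain chain identifier.
#' @return An [atom_model] with one P atom per residue (residue U).
#' @export
p_trace <- function(n_res = NULL, spacing = 5.9, chain = "A") {
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("'spacing' must be positive")
  if (is.null(n_res)) n_res <- length(spacing) + 1L
  stopifnot(n_res >= 2L)
  gaps <- if (length(spacing) == 1L) rep(spacing, n_res - 1L) else spacing
  if (length(gaps) != n_res - 1L)
    stop("'spacing' must be scalar or length n_res - 1")
  atom_model(data.frame(
    chain = chain, resno = seq_len(n_res), resid = "U", elety = "P",
    elesy = "P", x = cumsum(c(0, gaps)), y = 0, z = 0,
    stringsAsFactors = FALSE))
}

#' Perturb model coordinates with Gaussian noise
#'
#' @param model an [atom_model].
#' @param sd coordinate noise standard deviation in Angstrom.
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (convenient inside an outer seeded block).
#' @return The perturbed [atom_model].
#' @export
perturb_model <- function(model, sd = 0.1, seed = NULL) {
  stopifnot(inherits(model, "atom_model"))
  a <- model$atoms
  jitter <- function() matrix(stats::rnorm(3 * nrow(a), sd = sd), ncol = 3)
  j <- if (is.null(seed)) jitter() else with_seed(seed, jitter())
  a$x <- a$x + j[, 1]; a$y <- a$y + j[, 2]; a$z <- a$z + j[, 3]
  atom_model(a)
}
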