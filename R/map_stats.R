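#' Density histogram of a map
#'
#' Equal-width bins spanning the density range, right-open except the last
#' bin which is closed, so that counts always sum to the voxel count. A
#' constant map puts every voxel in a single bin.
#'
#' @param map a [density_map].
#' @param n_bins number of bins (>= 1).
#' @return A list with `breaks` (length `n_bins + 1`), `mids` and `counts`.
#' @export
density_histogram <- function(map, n_bins = 128L) {
  stopifnot(inherits(map, "density_map"))
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("'n_bins' must be >= 1")
  x <- as.vector(map$data)
  lo <- min(x); hi <- max(x)
  if (hi > lo) {
    width <- (hi - lo) / n_bins
    idx <- pmin(as.integer(floor((x - lo) / width)) + 1L, n_bins)
  } else {
    idx <- rep(1L, length(x))
  }
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  list(breaks = breaks, mids = (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2,
       counts = tabulate(idx, nbins = n_bins))
}

#' Rotationally averaged power spectrum
#'
#' Mean squared Fourier amplitude per spatial-frequency shell, with shells
#' as in [compute_fsc()]. The DC term is reported separately in `dc_power`.
#'
#' @param map a [density_map] with near-cubic voxels.
#' @return An object of class `radial_spectrum`: list with `frequencies`
#'   (1/A, shell centers, DC excluded), `power`, `shell_counts`, `dc_power`
#'   and `nyquist`.
#' @export
rotational_power_spectrum <- function(map) {
  stopifnot(inherits(map, "density_map"))
  check_cubic_voxels(map)
  sh <- fourier_shells(dim(map$data), map$voxel_size)
  p <- shell_sums(Mod(stats::fft(map$data))^2, sh) / pmax(sh$n_full, 1)
  structure(list(frequencies = sh$freq[-1L], power = p[-1L],
                 shell_counts = sh$n_unique[-1L], dc_power = p[1L],
                 nyquist = sh$nyquist),
            class = "radial_spectrum")
}

#' Enclosed volume versus contour level
#'
#' The volume at a level is the number of voxels with density at or above
#' the level times the voxel volume; it is non-increasing in the level, and
#' equals the full box volume at any level at or below the global minimum.
#'
#' @param map a [density_map].
#' @param levels numeric vector of density thresholds (map units); sorted
#'   ascending in the result.
#' @return An object of class `contour_curve`: list with `levels` and
#'   `volumes` (A^3).
#' @export
volume_vs_contour <- function(map, levels) {
  stopifnot(inherits(map, "density_map"))
  levels <- as.numeric(levels)
  if (any(!is.finite(levels))) stop("contour levels must be finite")
  levels <- sort(levels)
  x <- sort(as.vector(map$data))
  n <- length(x)
  # voxels >= level via binary search on the sorted densities
  counts <- n - findInterval(levels, x, left.open = TRUE)
  structure(list(levels = levels, volumes = counts * voxel_volume(map)),
            class = "contour_curve")
}

#' Orthogonal projections of a map
#'
#' Sums the density along each canonical axis. Raw sums are retained;
#' `scaled` holds copies normalized to the unit interval for rendering
#' (constant projections scale to 0).
#'
#' @param map a [density_map].
#' @return A list with `raw` and `scaled`, each a list of three matrices
#'   `along_x` (y by z), `along_y` (x by z) and `along_z` (x by y).
#' @export
orthogonal_projections <- function(map) {
  stopifnot(inherits(map, "density_map"))
  raw <- list(along_x = apply(map$data, c(2, 3), sum),
              along_y = apply(map$data, c(1, 3), sum),
              along_z = apply(map$data, c(1, 2), sum))
  unit <- function(p) {
    r <- range(p)
    if (r[2] > r[1]) (p - r[1]) / (r[2] - r[1]) else p * 0
  }
  list(raw = raw, scaled = lapply(raw, unit))
}

#' Central slices of a map
#'
#' The plane at 0-based index `floor(N/2)` along each axis (for even N this
#' is the N/2-th plane, 0-based).
#'
#' @param map a [density_map].
#' @return A list of three matrices `slice_x` (y by z plane), `slice_y`
#'   (x by z) and `slice_z` (x by y).
#' @export
central_slices <- function(map) {
  stopifnot(inherits(map, "density_map"))
  d <- dim(map$data)
  i <- d %/% 2L + 1L   # 0-based floor(N/2) in 1-based indexing
  list(slice_x = map$data[i[1L], , ],
       slice_y = map$data[, i[2L], ],
       slice_z = map$data[, , i[3L]])
}
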