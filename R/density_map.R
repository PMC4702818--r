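#' Construct a density map object
#'
#' A `density_map` is the unit of all map computations in emval: a 3D scalar
#' field of density values together with the voxel spacing, the position of
#' the first voxel in the orthogonal Angstrom frame, and summary statistics.
#' Data are always held in canonical axis order (x fastest, then y, then z);
#' [read_ccp4()] permutes file axes on load so that downstream code never has
#' to think about axis conventions.
#'
#' @param data 3D numeric array of density values (arbitrary units).
#' @param voxel_size voxel edge lengths in Angstrom, length-3 numeric
#'   (a scalar is recycled). All components must be positive.
#' @param origin position of the first voxel (index 0,0,0) in Angstrom,
#'   length-3 numeric.
#' @param axis_order the axis permutation of the source file mapping file
#'   axes (column, row, section) to crystal axes (x, y, z). Informational:
#'   `data` itself is always canonical.
#' @param origin_source how the origin was determined: `"explicit"` when set
#'   directly or taken from the Angstrom-valued header origin fields,
#'   `"start_index"` when derived as start index times voxel size.
#' @return An object of class `density_map` with elements `data`,
#'   `voxel_size`, `origin`, `axis_order`, `origin_source` and
#'   `header_stats` (min, max, mean, rms recomputed from `data`).
#' @seealso [read_ccp4()], [write_ccp4()], [recompute_stats()]
#' @export
density_map <- function(data, voxel_size = c(1, 1, 1), origin = c(0, 0, 0),
                        axis_order = 1:3,
                        origin_source = c("explicit", "start_index")) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  if (any(dim(data) < 1L))
    stop("all three map dimensions must be >= 1")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("'voxel_size' components must be positive and finite")
  if (any(!is.finite(origin)))
    stop("'origin' components must be finite")
  axis_order <- as.integer(axis_order)
  if (!identical(sort(axis_order), 1:3))
    stop("'axis_order' must be a permutation of 1:3")
  storage.mode(data) <- "double"
  m <- structure(
    list(data = data, voxel_size = voxel_size, origin = origin,
         axis_order = axis_order, origin_source = match.arg(origin_source),
         header_stats = NULL),
    class = "density_map")
  m$header_stats <- recompute_stats(m)
  m
}

#' Recompute map summary statistics
#'
#' Returns the minimum, maximum, mean and root-mean-square deviation about
#' the mean of the density values. These are the statistics carried in the
#' map header; emval always trusts the data over a stored header (see
#' [read_ccp4()]).
#'
#' @param map a `density_map`, or a bare numeric array.
#' @return A list with elements `min`, `max`, `mean`, `rms`.
#' @export
recompute_stats <- function(map) {
  x <- if (inherits(map, "density_map")) map$data else map
  mu <- mean(x)
  list(min = min(x), max = max(x), mean = mu,
       rms = sqrt(mean((x - mu)^2)))
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$data)
  s <- x$header_stats
  cat(sprintf("density_map: %d x %d x %d voxels\n", d[1], d[2], d[3]))
  cat(sprintf("  voxel size (A): %.4g %.4g %.4g\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  origin (A): %.4g %.4g %.4g  [%s]\n",
              x$origin[1], x$origin[2], x$origin[3], x$origin_source))
  cat(sprintf("  density: min %.4g  max %.4g  mean %.4g  rms %.4g\n",
              s$min, s$max, s$mean, s$rms))
  invisible(x)
}

# voxel volume in A^3
voxel_volume <- function(map) prod(map$voxel_size)

#' Round doubles through 32-bit float representation
#'
#' Maps each value to the nearest IEEE 754 single-precision number and back.
#' Useful for predicting exactly what a mode-2 CCP4/MRC file will hold: data
#' snapped with `float32()` survive [write_ccp4()] / [read_ccp4()] bit-exactly.
#'
#' @param x numeric vector or array.
#' @return `x` rounded to float32 precision, with dimensions preserved.
#' @export
float32 <- function(x) {
  r <- writeBin(as.numeric(x), raw(), size = 4L)
  y <- readBin(r, "numeric", n = length(x), size = 4L)
  if (!is.null(dim(x))) array(y, dim(x)) else y
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}
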