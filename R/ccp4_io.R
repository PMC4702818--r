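#' Read a CCP4/MRC density map
#'
#' Parses the 1024-byte CCP4/MRC header, reads the data block (modes 0, 1
#' and 2: signed 8-bit, signed 16-bit and 32-bit float), skips any extended
#' header, and returns a [density_map] in canonical axis order (x fastest).
#' Voxel size is cell length divided by grid sampling per crystal axis.
#'
#' The origin is taken from the Angstrom-valued MRC2000 origin fields when
#' any of them is non-zero, otherwise from the start indices times the voxel
#' size; `origin_source` records which. Header statistics are compared with
#' statistics recomputed from the data; on disagreement a warning is issued
#' and the recomputed values win.
#'
#' @param path path to an existing map file.
#' @return A [density_map].
#' @seealso [write_ccp4()]
#' @export
read_ccp4 <- function(path) {
  if (!file.exists(path)) stop("map file not found: ", path)
  fsize <- file.info(path)$size
  if (fsize < 1024)
    stop("truncated header: file is ", fsize, " bytes, a CCP4/MRC header needs 1024")
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 1024L)

  read_words <- function(endian) {
    list(i = readBin(hdr, "integer", n = 56L, size = 4L, endian = endian),
         f = readBin(hdr, "numeric", n = 56L, size = 4L, endian = endian))
  }
  plausible <- function(w) {
    d <- w$i[1:3]
    all(is.finite(d)) && all(d >= 1) && all(d <= 100000L) && w$i[4] %in% 0:6
  }
  endian <- "little"
  w <- read_words(endian)
  if (!plausible(w)) {
    endian <- "big"
    w <- read_words(endian)
    if (!plausible(w))
      stop("malformed header: grid dimensions NC/NR/NS (",
           paste(readBin(hdr, "integer", 3L, 4L, endian = "little"), collapse = ","),
           ") are implausible in either byte order")
  }

  dims_file <- w$i[1:3]
  mode <- w$i[4]
  if (!mode %in% c(0L, 1L, 2L))
    stop("unsupported mode: MODE = ", mode, " (modes 0, 1, 2 supported)")
  nstart_file <- w$i[5:7]
  grid <- w$i[8:10]
  cell <- w$f[11:13]
  axis_map <- w$i[17:19]
  if (all(axis_map == 0L)) axis_map <- 1:3
  if (!identical(sort(axis_map), 1:3))
    stop("malformed header: MAPC/MAPR/MAPS = (",
         paste(axis_map, collapse = ","), ") is not a permutation of 1..3")
  hdr_stats <- list(min = w$f[20], max = w$f[21], mean = w$f[22],
                    rms = w$f[55])
  nsymbt <- w$i[24]
  if (!is.finite(nsymbt) || nsymbt < 0) nsymbt <- 0L
  origin_field <- w$f[50:52]

  bytes <- c(`0` = 1L, `1` = 2L, `2` = 4L)[[as.character(mode)]]
  nvox <- prod(as.double(dims_file))
  expected <- 1024 + nsymbt + nvox * bytes
  if (fsize < expected)
    stop("truncated data block: need ", expected, " bytes for a ",
         paste(dims_file, collapse = "x"), " mode-", mode,
         " map, file has ", fsize)

  if (nsymbt > 0) invisible(readBin(con, "raw", nsymbt))
  data <- switch(as.character(mode),
    `0` = readBin(con, "integer", n = nvox, size = 1L, signed = TRUE,
                  endian = endian),
    `1` = readBin(con, "integer", n = nvox, size = 2L, signed = TRUE,
                  endian = endian),
    `2` = readBin(con, "numeric", n = nvox, size = 4L, endian = endian))
  if (length(data) < nvox)
    stop("truncated data block: read ", length(data), " of ", nvox, " voxels")

  arr <- array(as.double(data), dim = dims_file)
  # file axes (col,row,sec) carry crystal axes axis_map; permute to x,y,z
  arr <- aperm(arr, order(axis_map))

  # grid sampling and cell are already in crystal-axis order
  if (any(grid <= 0)) grid <- dim(arr)
  voxel <- cell / grid
  if (any(!is.finite(voxel)) || any(voxel <= 0)) {
    warning("cell dimensions missing from header; assuming 1 A voxels")
    voxel <- c(1, 1, 1)
  }
  nstart <- nstart_file[order(axis_map)]
  if (any(origin_field != 0)) {
    origin <- origin_field
    origin_source <- "explicit"
  } else {
    origin <- nstart * voxel
    origin_source <- "start_index"
  }

  m <- density_map(arr, voxel_size = voxel, origin = origin,
                   axis_order = axis_map, origin_source = origin_source)
  rs <- m$header_stats
  tol <- 1e-4 * max(1, rs$rms, rs$max - rs$min)
  if (abs(hdr_stats$mean - rs$mean) > tol ||
      abs(hdr_stats$min - rs$min) > tol ||
      abs(hdr_stats$max - rs$max) > tol)
    warning(sprintf(paste0("header statistics disagree with data ",
                           "(header min/max/mean %.6g/%.6g/%.6g, ",
                           "data %.6g/%.6g/%.6g); using recomputed values"),
                    hdr_stats$min, hdr_stats$max, hdr_stats$mean,
                    rs$min, rs$max, rs$mean))
  m
}

#' Write a density map as a mode-2 CCP4/MRC file
#'
#' Writes a 32-bit float (mode 2) map with header statistics recomputed from
#' the data. Data are stored in file axis order `axis_order` (default
#' canonical x/y/z); [read_ccp4()] restores canonical order regardless. The
#' origin is written to the Angstrom-valued MRC2000 origin fields, start
#' indices are zero.
#'
#' Header and data values pass through 32-bit float storage, so values are
#' reproduced at single precision; inputs snapped with [float32()] round-trip
#' bit-exactly.
#'
#' @param map a [density_map].
#' @param path output file path.
#' @param axis_order permutation of 1:3 giving the crystal axis stored on
#'   each file axis (column, row, section). Mainly useful for producing
#'   permuted test files.
#' @param sanitize if `TRUE`, non-finite densities are replaced with 0;
#'   otherwise they are an error.
#' @return Invisibly, `path`.
#' @export
write_ccp4 <- function(map, path, axis_order = 1:3, sanitize = FALSE) {
  stopifnot(inherits(map, "density_map"))
  axis_order <- as.integer(axis_order)
  if (!identical(sort(axis_order), 1:3))
    stop("'axis_order' must be a permutation of 1:3")
  data <- map$data
  if (!all(is.finite(data))) {
    if (!sanitize)
      stop("map contains non-finite densities; use sanitize = TRUE to zero them")
    data[!is.finite(data)] <- 0
  }
  s <- recompute_stats(data)
  dims <- dim(data)
  cell <- map$voxel_size * dims

  D <- aperm(data, axis_order)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(dim(D))                     # 1-3   NC NR NS
  wi(2L)                         # 4     MODE
  wi(c(0L, 0L, 0L))              # 5-7   NCSTART NRSTART NSSTART
  wi(dims)                       # 8-10  MX MY MZ (crystal-axis order)
  wf(cell)                       # 11-13 cell lengths (A)
  wf(c(90, 90, 90))              # 14-16 cell angles
  wi(axis_order)                 # 17-19 MAPC MAPR MAPS
  wf(c(s$min, s$max, s$mean))    # 20-22
  wi(c(1L, 0L))                  # 23-24 ISPG NSYMBT
  wi(integer(25L))               # 25-49 extra
  wf(map$origin)                 # 50-52 ORIGIN (A)
  writeBin(charToRaw("MAP "), con)            # 53
  writeBin(as.raw(c(0x44, 0x41, 0, 0)), con)  # 54 MACHST little-endian
  wf(s$rms)                      # 55
  wi(0L)                         # 56 NLABL
  writeBin(raw(800L), con)       # labels
  wf(as.numeric(D))
  invisible(path)
}
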