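#' Compute the Fourier Shell Correlation between two half-maps
#'
#' The FSC between two volumes is the normalized cross-correlation of their
#' Fourier transforms over concentric shells of spatial frequency:
#' \deqn{FSC(s) = \Re\sum_s F_a \bar F_b \; / \;
#'   \sqrt{\sum_s |F_a|^2 \sum_s |F_b|^2}}
#' with shells one reciprocal-grid step wide. The DC term is reported as its
#' own shell at frequency 0; it is excluded from resolution estimation (see
#' [estimate_resolution()]). `shell_counts` holds the number of independent
#' Fourier voxels per shell, counting each conjugate-symmetric pair of the
#' real-input transform once.
#'
#' @param half_map_a,half_map_b two [density_map]s on identical grids with
#'   matching (relative tolerance 1e-3) and near-cubic voxel sizes.
#' @return An object of class `fsc_curve`: list with `frequencies` (1/A,
#'   ascending, first element 0 for the DC shell), `correlations`,
#'   `shell_counts` and `nyquist` (1/A).
#' @export
compute_fsc <- function(half_map_a, half_map_b) {
  stopifnot(inherits(half_map_a, "density_map"),
            inherits(half_map_b, "density_map"))
  da <- dim(half_map_a$data); db <- dim(half_map_b$data)
  if (!identical(da, db))
    stop("grid mismatch: ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"))
  va <- half_map_a$voxel_size; vb <- half_map_b$voxel_size
  if (any(abs(va - vb) / va > 1e-3))
    stop("voxel-size mismatch: (", paste(signif(va, 6), collapse = ", "),
         ") vs (", paste(signif(vb, 6), collapse = ", "), ") A")
  check_cubic_voxels(half_map_a)
  if (all(half_map_a$data == 0) || all(half_map_b$data == 0))
    stop("all-zero map: FSC normalization undefined")

  sh <- fourier_shells(da, va)
  fa <- stats::fft(half_map_a$data)
  fb <- stats::fft(half_map_b$data)
  num <- shell_sums(Re(fa * Conj(fb)), sh)
  pa <- shell_sums(Mod(fa)^2, sh)
  pb <- shell_sums(Mod(fb)^2, sh)
  den <- sqrt(pa * pb)
  fsc <- ifelse(den > 0, num / den, NA_real_)

  structure(list(frequencies = sh$freq, correlations = fsc,
                 shell_counts = sh$n_unique, nyquist = sh$nyquist),
            class = "fsc_curve")
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("fsc_curve: %d shells, frequencies 0..%.4g 1/A (Nyquist %.4g)\n",
              length(x$frequencies), max(x$frequencies), x$nyquist))
  invisible(x)
}

#' Per-shell FSC threshold for a named criterion
#'
#' @param criterion criterion name (see [estimate_resolution()]).
#' @param n per-shell independent Fourier voxel counts.
#' @return Numeric vector of thresholds, one per shell.
#' @export
fsc_threshold <- function(criterion, n) {
  switch(criterion,
    "fixed-0.5" = rep(0.5, length(n)),
    "fixed-0.143" = rep(0.143, length(n)),
    "half-bit" = (0.2071 + 1.9102 / sqrt(n)) / (1.2071 + 0.9102 / sqrt(n)),
    "three-sigma" = 3 / sqrt(n / 2),
    stop("unknown criterion: ", criterion))
}

normalize_criterion <- function(criterion) {
  key <- gsub("[^a-z0-9.]", "", tolower(criterion))
  out <- c("0.5" = "fixed-0.5", "fixed0.5" = "fixed-0.5",
           "0.143" = "fixed-0.143", "fixed0.143" = "fixed-0.143",
           "halfbit" = "half-bit", "3sigma" = "three-sigma",
           "threesigma" = "three-sigma")[key]
  if (is.na(out)) stop("unknown criterion: ", criterion)
  unname(out)
}

#' Estimate resolution from an FSC curve
#'
#' Scans the curve from low to high frequency (excluding the DC shell) for
#' the first shell where the correlation falls below the criterion
#' threshold, and refines the crossing by linear interpolation between
#' adjacent shell centers (interpolating the threshold too for the
#' count-dependent criteria). The estimated resolution is the reciprocal of
#' the crossing frequency. A curve that never crosses yields
#' `reached = FALSE` with the Nyquist resolution as a bound, not an error.
#'
#' Criteria: `fixed-0.5` and `fixed-0.143` are constant thresholds;
#' `half-bit` uses \eqn{(0.2071 + 1.9102/\sqrt{n}) / (1.2071 +
#' 0.9102/\sqrt{n})} and `three-sigma` uses \eqn{3/\sqrt{n/2}}, with n the
#' per-shell independent voxel count (no symmetry correction).
#'
#' @param curve an `fsc_curve` from [compute_fsc()] or [read_fsc_xml()].
#' @param criterion one of `"fixed-0.5"`, `"fixed-0.143"`, `"half-bit"`,
#'   `"three-sigma"` (short aliases `"0.5"`, `"0.143"`, `"halfbit"`,
#'   `"3sigma"` accepted).
#' @return An object of class `resolution_estimate`: list with `criterion`,
#'   `resolution` (A, `NA` when not reached), `crossing_frequency` (1/A or
#'   `NA`), `reached`, and `resolution_bound` (A at Nyquist, only meaningful
#'   when not reached).
#' @export
estimate_resolution <- function(curve, criterion = "fixed-0.143") {
  stopifnot(inherits(curve, "fsc_curve"))
  criterion <- normalize_criterion(criterion)
  f <- curve$frequencies
  y <- curve$correlations
  use <- f > 0 & !is.na(y)           # DC and degenerate shells excluded
  f <- f[use]; y <- y[use]
  n <- curve$shell_counts[use]
  if (criterion %in% c("half-bit", "three-sigma") && any(is.na(n)))
    stop("criterion '", criterion, "' needs per-shell voxel counts, ",
         "absent from this curve")
  thr <- fsc_threshold(criterion, n)
  d <- y - thr
  below <- which(d < 0)
  if (length(below) == 0L) {
    res <- structure(list(criterion = criterion, resolution = NA_real_,
                          crossing_frequency = NA_real_, reached = FALSE,
                          resolution_bound = 1 / curve$nyquist),
                     class = "resolution_estimate")
    return(res)
  }
  k <- below[1L]
  if (k == 1L) {
    fc <- f[1L]
  } else {
    t <- d[k - 1L] / (d[k - 1L] - d[k])
    fc <- f[k - 1L] + t * (f[k] - f[k - 1L])
  }
  structure(list(criterion = criterion, resolution = 1 / fc,
                 crossing_frequency = fc, reached = TRUE,
                 resolution_bound = 1 / curve$nyquist),
            class = "resolution_estimate")
}

#' @export
print.resolution_estimate <- function(x, ...) {
  if (x$reached)
    cat(sprintf("%s: %.3f A (crossing at %.5g 1/A)\n",
                x$criterion, x$resolution, x$crossing_frequency))
  else
    cat(sprintf("%s: not reached (better than %.3f A at Nyquist)\n",
                x$criterion, x$resolution_bound))
  invisible(x)
}

#' Estimate resolution under several criteria at once
#'
#' @param curve an `fsc_curve`.
#' @param criteria character vector of criterion names.
#' @return A data frame with one row per criterion: `criterion`,
#'   `resolution`, `crossing_frequency`, `reached`.
#' @export
estimate_resolutions <- function(curve,
                                 criteria = c("fixed-0.5", "fixed-0.143",
                                              "half-bit", "three-sigma")) {
  rows <- lapply(criteria, function(cr) {
    e <- estimate_resolution(curve, cr)
    data.frame(criterion = e$criterion, resolution = e$resolution,
               crossing_frequency = e$crossing_frequency,
               reached = e$reached, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write an FSC curve in the standardized deposition XML dialect
#'
#' Root element `fsc` with `title`, `xaxis` and `yaxis` attributes; one
#' `coordinate` child per shell holding `x` (spatial frequency, 1/A) and `y`
#' (correlation) children, both at 6 significant digits, in ascending x.
#'
#' @param curve an `fsc_curve`.
#' @param path output file path.
#' @param title curve title attribute.
#' @return Invisibly, `path`.
#' @export
write_fsc_xml <- function(curve, path, title = "Fourier Shell Correlation") {
  stopifnot(inherits(curve, "fsc_curve"))
  doc <- xml2::xml_new_root("fsc", title = title,
                            xaxis = "Spatial frequency (1/Angstrom)",
                            yaxis = "Correlation coefficient")
  for (i in seq_along(curve$frequencies)) {
    co <- xml2::xml_add_child(doc, "coordinate")
    xml2::xml_add_child(co, "x", formatC(curve$frequencies[i],
                                         digits = 6, format = "g"))
    xml2::xml_add_child(co, "y", formatC(curve$correlations[i],
                                         digits = 6, format = "g"))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read an FSC curve from the deposition XML dialect
#'
#' Inverse of [write_fsc_xml()] up to the stored precision. Per-shell voxel
#' counts are not part of the exchange format, so count-based resolution
#' criteria are unavailable on a re-read curve.
#'
#' @param path path to an FSC XML document.
#' @return An `fsc_curve` with `shell_counts = NA` and `nyquist` set to the
#'   highest stored frequency.
#' @export
read_fsc_xml <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "fsc")
    stop("not an FSC document: root element is <", xml2::xml_name(doc), ">")
  coords <- xml2::xml_find_all(doc, "./coordinate")
  if (length(coords) == 0L) stop("no coordinates in FSC document")
  xs <- xml2::xml_find_first(coords, "./x")
  ys <- xml2::xml_find_first(coords, "./y")
  if (any(is.na(xs)) || any(is.na(ys)))
    stop("coordinate element missing x or y child")
  f <- as.numeric(xml2::xml_text(xs))
  y <- as.numeric(xml2::xml_text(ys))
  if (any(is.na(f)) || any(is.na(y)))
    stop("non-numeric x or y value in FSC document")
  if (any(diff(f) <= 0))
    stop("non-monotone frequencies in FSC document")
  structure(list(frequencies = f, correlations = y,
                 shell_counts = rep(NA_real_, length(f)),
                 nyquist = max(f)),
            class = "fsc_curve")
}
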