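# Static PNG renderings of the visual-analysis statistics. Kept deliberately
# plain: these are the quick-look figures of a validation run, not
# publication graphics.

#' Plot an FSC curve
#'
#' Draws the curve with the fixed 0.5 and 0.143 threshold lines and marks
#' reached resolution crossings.
#'
#' @param curve an `fsc_curve`.
#' @param path optional PNG output path; when `NULL` draws on the current
#'   device.
#' @return Invisibly, `path` (or `NULL`).
#' @export
plot_fsc_curve <- function(curve, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 800, height = 600)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(curve$frequencies, curve$correlations, type = "l",
                 lwd = 2, ylim = c(min(0, curve$correlations), 1),
                 xlab = "Spatial frequency (1/Å)",
                 ylab = "Fourier Shell Correlation",
                 main = "FSC")
  graphics::abline(h = c(0.5, 0.143), lty = c(2, 3), col = "grey40")
  for (cr in c("fixed-0.5", "fixed-0.143")) {
    e <- estimate_resolution(curve, cr)
    if (e$reached)
      graphics::points(e$crossing_frequency,
                       fsc_threshold(cr, 1)[1], pch = 19, col = "red")
  }
  invisible(path)
}

#' Plot a density histogram
#' @param hist result of [density_histogram()].
#' @param path optional PNG output path.
#' @return Invisibly, `path`.
#' @export
plot_density_histogram <- function(hist, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 800, height = 600)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(hist$mids, hist$counts, type = "h", log = "",
                 xlab = "Density (map units)", ylab = "Voxel count",
                 main = "Map density distribution")
  invisible(path)
}

#' Plot enclosed volume versus contour level
#' @param curve a `contour_curve` from [volume_vs_contour()].
#' @param path optional PNG output path.
#' @return Invisibly, `path`.
#' @export
plot_contour_curve <- function(curve, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 800, height = 600)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(curve$levels, curve$volumes, type = "l", lwd = 2,
                 xlab = "Contour level (map units)",
                 ylab = "Enclosed volume (Å³)",
                 main = "Volume vs contour level")
  invisible(path)
}

#' Render orthogonal projections or central slices as PNG
#' @param images list of three matrices (raw or scaled).
#' @param path PNG output path.
#' @param titles panel titles.
#' @return Invisibly, `path`.
#' @export
plot_image_triptych <- function(images, path,
                                titles = names(images)) {
  grDevices::png(path, width = 1200, height = 420)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  for (k in seq_along(images)) {
    graphics::image(images[[k]], axes = FALSE, col = grDevices::gray.colors(256),
                    main = if (is.null(titles)) "" else titles[k])
  }
  invisible(path)
}
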