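# Figure helpers: release-probability maps and profile plots.

#' Render a per-AZ Pr heatmap onto a structural image
#'
#' Draws the structural channel in grayscale and overlays each AZ as a
#' circle coloured by its estimated Pr (dark blue = 0 to yellow = max), the
#' standard presentation of single-AZ release-probability maps.
#'
#' @param image structural channel matrix.
#' @param prmap a classified `pr_map`.
#' @param az `az_table` with positions for the mapped AZs.
#' @param pixel_size_um pixel size (um).
#' @param file optional PNG path; when given the plot is written there.
#' @param cex symbol size.
#' @return invisibly, the colour assigned to each AZ.
#' @export
plot_pr_map <- function(image, prmap, az, pixel_size_um = 0.138,
                        file = NULL, cex = 1) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 900)
    on.exit(grDevices::dev.off())
  }
  pal <- grDevices::hcl.colors(100, "viridis")
  pr <- prmap$pr_hat[match(az$az_id, prmap$az_id)]
  idx <- pmax(1L, pmin(100L, 1L + floor(99 * pr / max(pr, 1e-12))))
  cols <- pal[idx]
  graphics::par(mar = c(2, 2, 2, 1))
  graphics::image(z = t(image)[, nrow(image):1],
                  col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, asp = nrow(image) / ncol(image),
                  main = "AZ release-probability map")
  # convert micron positions to the [0,1] plot coordinates of image()
  px <- um_to_px(az$x_um, pixel_size_um) / ncol(image)
  py <- 1 - um_to_px(az$y_um, pixel_size_um) / nrow(image)
  graphics::points(px, py, col = cols, pch = 1, cex = cex, lwd = 2)
  invisible(cols)
}

#' Plot a two-channel PSD profile
#'
#' Line plot of the normalised channel-A and channel-B profiles versus
#' distance, with the ring call annotated.
#'
#' @param profile a `profile_result` (ring-processed or not).
#' @param file optional PNG path.
#' @return invisibly, `NULL`.
#' @export
plot_profile <- function(profile, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 700, height = 500)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(profile$distance_um, profile$chanA_norm, type = "l",
                 col = "red3", lwd = 2, ylim = c(0, 1),
                 xlab = "distance (um)", ylab = "normalised intensity")
  graphics::lines(profile$distance_um, profile$chanB_norm, col = "green4",
                  lwd = 2)
  if (!is.null(profile$dip_frac))
    graphics::legend("topright", bty = "n", legend = sprintf(
      "dip = %.2f%s", profile$dip_frac,
      if (isTRUE(profile$has_ring)) " (ring)" else ""))
  graphics::legend("topleft", bty = "n", lwd = 2,
                   col = c("red3", "green4"),
                   legend = c("channel A", "channel B"))
  invisible(NULL)
}
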