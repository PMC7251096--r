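## Visual-debug exports: pixel-track overlays and survival step plots.

#' Write a pixel-track contour overlay PNG
#'
#' Renders the plate with each pixel-level track's pixels tinted by zone
#' class (wall red, centre green, mixed yellow) over the grayscale frame,
#' for visual debugging of the motion-detection stage.
#'
#' @param frame grayscale background frame.
#' @param tracks list of [PixelTrack-class].
#' @param path output PNG path.
#' @return Invisibly, the path.
#' @export
writeTrackOverlayPng <- function(frame, tracks, path) {
  g <- frame / 255
  img <- array(rep(g, 3), c(dim(frame), 3))
  tint <- c(WALL = "red", CENTER = "green", MIXED = "yellow")
  for (tr in tracks) {
    col <- grDevices::col2rgb(tint[[tr@zoneClass]]) / 255
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[tr@pixels] <- 0.5 * plane[tr@pixels] + 0.5 * col[ch]
      img[, , ch] <- plane
    }
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Write a survival step plot PNG
#'
#' Kaplan-Meier-style per-day survival fraction for one or more lifespan
#' curves, pooled with [survivalFraction()].
#'
#' @param curves a [LifespanCurve-class] or list of them.
#' @param path output PNG path.
#' @param main plot title.
#' @return Invisibly, the path.
#' @export
writeSurvivalPlotPng <- function(curves, path, main = "Survival") {
  if (is(curves, "LifespanCurve")) curves <- list(curves)
  sf <- survivalFraction(curves)
  grDevices::png(path, width = 720, height = 480)
  on.exit(grDevices::dev.off())
  plot(sf$day, sf$fraction, type = "s", lwd = 2, ylim = c(0, 1),
       xlab = "assay day", ylab = "surviving fraction", main = main)
  invisible(path)
}
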