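# Quick-look map of tracks in the polar equal-area projection, coloured by
# per-segment wind support when segments are supplied (tailwind green,
# headwind red, as is conventional for these maps).

#' Plot tracks on a polar equal-area map
#'
#' @param tracks list of [track()]s
#' @param segments optional `segments` data.frame (same tracks) used to
#'   colour each segment by wind support
#' @param coast optional `coastline` object drawn as grey polygons
#' @param lon0 projection central meridian (default -156.65)
#' @param ... passed to [graphics::plot()]
#' @return invisibly, NULL
#' @export
plot_tracks <- function(tracks, segments = NULL, coast = NULL,
                        lon0 = -156.65, ...) {
  all_xy <- do.call(rbind, lapply(tracks, function(t) laea_polar(t$lon, t$lat, lon0)))
  graphics::plot(all_xy$x / 1000, all_xy$y / 1000, type = "n", asp = 1,
                 xlab = "x (km)", ylab = "y (km)", ...)
  if (!is.null(coast)) {
    for (poly in coast) {
      xy <- laea_polar(poly[, 1], poly[, 2], lon0)
      graphics::polygon(xy$x / 1000, xy$y / 1000, col = "grey85", border = "grey60")
    }
  }
  pal <- function(ws) {
    # headwind red through white to tailwind green
    z <- pmax(-10, pmin(10, ws)) / 10
    grDevices::rgb(1 - pmax(0, z), 1 - pmax(0, -z), 1 - abs(z))
  }
  for (t in tracks) {
    xy <- laea_polar(t$lon, t$lat, lon0)
    if (!is.null(segments)) {
      segs <- segments[segments$track == attr(t, "id"), , drop = FALSE]
      n <- min(nrow(xy) - 1, nrow(segs))
      graphics::segments(xy$x[1:n] / 1000, xy$y[1:n] / 1000,
                         xy$x[2:(n + 1)] / 1000, xy$y[2:(n + 1)] / 1000,
                         col = pal(segs$ws[1:n]), lwd = 2)
    } else {
      graphics::lines(xy$x / 1000, xy$y / 1000, col = "grey30")
    }
  }
  invisible(NULL)
}
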