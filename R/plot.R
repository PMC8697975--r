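#' Plot a time-frequency map (F-values or power)
#'
#' Image plot with time on the x-axis and frequency on the y-axis, a
#' labelled colorbar, and a vertical marker at the cue onset (t = 0).
#'
#' @param x an `ftf_map`, or a freqs x times numeric matrix.
#' @param channel channel index or label (for `ftf_map` input).
#' @param time_axis,freqs axes (taken from the map when available).
#' @param unit colorbar label; `"F-value"` for F-maps, `"AU"` for
#'   baseline-normalized power.
#' @param main title.
#' @param zlim color range; defaults to the finite data range.
#' @param ... ignored.
#' @return invisibly, the plotted matrix.
#' @export
plot_map <- function(x, channel = 1L, time_axis = NULL, freqs = NULL,
                     unit = "F-value", main = NULL, zlim = NULL, ...) {
  if (inherits(x, "ftf_map")) {
    if (is.character(channel)) channel <- match(channel, x$channel_labels)
    m <- x$f_values[channel, , ]
    time_axis <- time_axis %||% x$time_axis
    freqs <- freqs %||% x$freqs
    main <- main %||% sprintf("FTF map, channel %s", x$channel_labels[channel])
  } else {
    m <- as.matrix(x)
    time_axis <- time_axis %||% seq_len(ncol(m))
    freqs <- freqs %||% seq_len(nrow(m))
    main <- main %||% ""
  }
  mf <- m; mf[!is.finite(mf)] <- NA
  zlim <- zlim %||% range(mf, na.rm = TRUE)
  if (zlim[1] == zlim[2]) zlim <- zlim + c(-0.5, 0.5)
  pal <- hcl.colors(64, "Viridis")
  op <- par(no.readonly = TRUE); on.exit(par(op))
  graphics::layout(matrix(1:2, 1), widths = c(5, 1))
  par(mar = c(4, 4, 2.5, 0.5))
  image(time_axis, freqs, t(mf), zlim = zlim, col = pal,
        xlab = "Time (s)", ylab = "Frequency (Hz)", main = main,
        useRaster = TRUE)
  abline(v = 0, col = "red", lwd = 1.5)
  # colorbar
  par(mar = c(4, 0.5, 2.5, 2.5))
  zseq <- seq(zlim[1], zlim[2], length.out = 64)
  image(1, zseq, matrix(zseq, 1), col = pal, axes = FALSE, xlab = "",
        ylab = "")
  axis(4, las = 1)
  graphics::mtext(unit, side = 3, line = 0.3, cex = 0.8)
  invisible(m)
}

#' @export
plot.ftf_map <- function(x, channel = 1L, ...) {
  plot_map(x, channel = channel, unit = "F-value", ...)
}

#' Plot a condition-mean TFR (one entry of [average_tfr_by_condition()])
#'
#' @param m channels x freqs x times array with `freqs` / `time_axis`
#'   attributes (as returned per condition by
#'   [average_tfr_by_condition()]).
#' @param channel channel index.
#' @param main title.
#' @param ... passed to [plot_map()].
#' @export
plot_tfr <- function(m, channel = 1L, main = NULL, ...) {
  plot_map(m[channel, , ], time_axis = attr(m, "time_axis"),
           freqs = attr(m, "freqs"), unit = "AU", main = main %||% "", ...)
}

#' @export
plot.topography <- function(x, main = NULL, zlim = NULL,
                            cex_points = 4, ...) {
  v <- x$channel_values
  zlim <- zlim %||% range(v)
  if (zlim[1] == zlim[2]) zlim <- zlim + c(-0.5, 0.5)
  pal <- hcl.colors(64, "Viridis")
  col <- pal[pmin(64, pmax(1, 1 + floor(63 * (v - zlim[1]) /
                                          (zlim[2] - zlim[1]))))]
  op <- par(no.readonly = TRUE); on.exit(par(op))
  par(mar = c(1, 1, 2.5, 1), pty = "s")
  plot(NA, xlim = c(-1.25, 1.25), ylim = c(-1.25, 1.25), axes = FALSE,
       xlab = "", ylab = "", asp = 1,
       main = main %||% sprintf("%g-%g Hz, %g-%g s (F-value)",
                                x$band[1], x$band[2],
                                x$window[1], x$window[2]))
  th <- seq(0, 2 * pi, length.out = 181)
  lines(cos(th), sin(th))
  lines(c(-0.08, 0, 0.08), c(0.995, 1.1, 0.995))        # nose
  points(x$positions$x, x$positions$y, pch = 21, bg = col,
         cex = cex_points)
  text(x$positions$x, x$positions$y, names(v), cex = 0.55)
  invisible(x)
}

#' Render an F-map or topography to a PNG file
#'
#' Writes a fixed-style figure; with identical input and style the pixel
#' content is reproducible across runs.
#'
#' @param map an `ftf_map`.
#' @param path output PNG path.
#' @param channel channel index or label.
#' @param width,height device size in pixels.
#' @return `path`, invisibly.
#' @export
render_map <- function(map, path, channel = 1L, width = 900, height = 600) {
  png(path, width = width, height = height)
  on.exit(dev.off())
  plot_map(map, channel = channel)
  invisible(path)
}

#' @rdname render_map
#' @param topo a `topography`.
#' @export
render_topography <- function(topo, path, width = 600, height = 600) {
  png(path, width = width, height = height)
  on.exit(dev.off())
  plot(topo)
  invisible(path)
}

#' Multi-channel grid of F-maps
#'
#' One panel per channel (shared color range), mirroring the standard
#' multi-channel overview figure.
#'
#' @param map an `ftf_map`.
#' @param channels channel indices (default all).
#' @param zlim shared color range.
#' @export
plot_channel_grid <- function(map, channels = NULL, zlim = NULL) {
  channels <- channels %||% seq_along(map$channel_labels)
  mf <- map$f_values[channels, , , drop = FALSE]
  mf[!is.finite(mf)] <- NA
  zlim <- zlim %||% range(mf, na.rm = TRUE)
  nc <- ceiling(sqrt(length(channels)))
  nr <- ceiling(length(channels) / nc)
  op <- par(no.readonly = TRUE); on.exit(par(op))
  par(mfrow = c(nr, nc), mar = c(2.5, 2.5, 1.5, 0.5))
  pal <- hcl.colors(64, "Viridis")
  for (i in seq_along(channels)) {
    image(map$time_axis, map$freqs, t(mf[i, , ]), zlim = zlim, col = pal,
          xlab = "", ylab = "", main = map$channel_labels[channels[i]],
          useRaster = TRUE)
    abline(v = 0, col = "red")
  }
  invisible(map)
}
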