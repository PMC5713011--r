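#' Severity color palette
#'
#' One fixed five-color palette shared by all renderers: noise-free blue,
#' low green, moderate yellow, hard red, other black.
#'
#' @return named character vector of colors for levels 0-4.
#' @export
severity_palette <- function() {
  c(`0` = "#1f77b4", `1` = "#2ca02c", `2` = "#ffcc00",
    `3` = "#d62728", `4` = "#000000")
}

#' Plot a noise map
#'
#' Draws each segment as a horizontal colored band at its severity level.
#' Optionally overlays the source ECG lead above the map.
#'
#' @param x a [noise_map()].
#' @param lead optional numeric ECG series to draw above the map.
#' @param fs sampling rate of `lead` (needed when `lead` is given).
#' @param ... ignored.
#' @return invisibly, `x`.
#' @export
plot.noise_map <- function(x, lead = NULL, fs = NULL, ...) {
  pal <- severity_palette()
  if (!is.null(lead)) {
    op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
    on.exit(graphics::par(op))
    tt <- x$start_s[1] + (seq_along(lead) - 1L) / fs
    graphics::plot(tt, lead, type = "l", xlab = "", ylab = "ECG (mV)")
  }
  xlim <- range(x$start_s, x$end_s)
  graphics::plot(NA, xlim = xlim, ylim = c(-0.5, 4.5), xlab = "time (s)",
                 ylab = "severity level", yaxt = "n")
  graphics::axis(2, at = 0:4, labels = names(severity_levels()), las = 1)
  for (i in seq_len(nrow(x)))
    graphics::segments(x$start_s[i], x$level[i], x$end_s[i], x$level[i],
                       col = pal[as.character(x$level[i])], lwd = 6, lend = 1)
  invisible(x)
}

#' Plot noise bars
#'
#' Stacked per-bar severity fractions; lower (upper) portions of each bar
#' carry the lower (harder) levels. Blank bars are left empty.
#'
#' @param x a `noise_bars` data frame from [build_noise_bars()].
#' @param ... ignored.
#' @return invisibly, `x`.
#' @export
plot.noise_bars <- function(x, ...) {
  pal <- severity_palette()
  frac <- t(as.matrix(x[paste0("frac_level", 0:4)]))
  frac[is.na(frac)] <- 0
  graphics::barplot(frac, col = pal, border = NA, space = 0.1,
                    names.arg = x$bar_index,
                    xlab = sprintf("bar (%g s each)", attr(x, "bar_s")),
                    ylab = "fraction of labeled time")
  graphics::legend("topright", legend = names(severity_levels()),
                   fill = pal, bty = "n", cex = 0.8)
  invisible(x)
}

#' Render a noise map or noise bars to an image file
#'
#' @param x a [noise_map()] or `noise_bars` object.
#' @param path output path ending in `.png` or `.svg`.
#' @param width,height device size in pixels (png) or inches (svg).
#' @param ... passed to the plot method.
#' @return invisibly, `path`.
#' @export
render_figure <- function(x, path, width = 1000, height = 400, ...) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") grDevices::png(path, width = width, height = height)
  else if (ext == "svg") grDevices::svg(path, width = width / 100, height = height / 100)
  else stop("unsupported figure format: use .png or .svg", call. = FALSE)
  on.exit(grDevices::dev.off())
  graphics::plot(x, ...)
  invisible(path)
}
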