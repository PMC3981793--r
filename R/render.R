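# Rendering of the dotted scan plot: a scatter at (x, y) = (left-most,
# right-most window position), grayscale level 1 - intensity on white, so
# unchanged windows are invisible and the largest structural change is
# black.  Dense dark clusters flag candidate thermometer segments.

#' Render the scan dot plot
#'
#' @param result a `scan_result`.
#' @param path output image path; format follows the extension (`.png` or
#'   `.svg`) unless `format` overrides it.
#' @param format `"auto"`, `"png"` or `"svg"`.
#' @param width,height canvas size in inches.
#' @param dpi raster resolution (png only).
#' @param marker_size dot size in points.
#' @param axis_labels draw axis titles and the plot title.
#' @return `path`, invisibly.
#' @export
render_dotplot <- function(result, path, format = c("auto", "png", "svg"),
                           width = 6, height = 6, dpi = 150,
                           marker_size = 0.9, axis_labels = TRUE) {
  stopifnot(inherits(result, "scan_result"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("png", "svg")) ext else "png"
  }
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0)
    stop(sprintf("output path is not writable: %s", path))
  L <- result$sequence_length
  visible <- result$dots[result$dots$intensity > 0, , drop = FALSE]
  g <- ggplot2::ggplot(visible, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$intensity),
                        size = marker_size, show.legend = FALSE) +
    ggplot2::scale_colour_gradient(low = "white", high = "black",
                                   limits = c(0, 1)) +
    ggplot2::scale_x_continuous(limits = c(1, L)) +
    ggplot2::scale_y_continuous(limits = c(1, L)) +
    ggplot2::theme_bw() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
  if (axis_labels) {
    cfg <- result$config
    g <- g + ggplot2::labs(
      x = "left-most window position (nt)",
      y = "right-most window position (nt)",
      title = sprintf("%s: %g C vs %g C, windows %d-%d, %s",
                      result$sequence_id, cfg$t1$celsius, cfg$t2$celsius,
                      cfg$wmin, cfg$wmax, cfg$mode)
    )
  } else {
    g <- g + ggplot2::labs(x = NULL, y = NULL)
  }
  if (format == "png") {
    grDevices::png(path, width = width, height = height, units = "in", res = dpi)
  } else {
    grDevices::svg(path, width = width, height = height)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  print(g)
  invisible(path)
}

#' @importFrom ggplot2 .data
NULL
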