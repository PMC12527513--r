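# Renderers. These draw layouts; they never recompute a layout number.

marc_palette <- function() {
  c(negative = "#B2182B", positive = "#2166AC", zero = "#777777")
}

marc_shading <- function(xlim) {
  tibble::tibble(
    xmin = c(xlim[1], 0), xmax = c(0, xlim[2]),
    fill = c("negative", "positive")
  )
}

x_range <- function(layout) {
  xs <- c(layout$marks$x, 0)
  if (!is.null(layout$cloud)) xs <- c(xs, layout$cloud$dots$x)
  if ("ci_low" %in% names(layout$marks)) {
    xs <- c(xs, layout$marks$ci_low, layout$marks$ci_high)
  }
  range(xs) + c(-0.05, 0.05) * diff(range(xs))
}

marc_study_panel <- function(layout, xlim, ylim, palette, show_cloud = FALSE) {
  shade <- marc_shading(xlim)
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf, fill = .data$fill),
      alpha = 0.08, show.legend = FALSE
    ) +
    ggplot2::geom_vline(xintercept = layout$zero_line, linetype = "dashed",
                        color = "grey40") +
    ggplot2::geom_point(
      data = layout$marks,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$area,
                   color = .data$color),
      show.legend = FALSE
    ) +
    ggplot2::scale_size_area(max_size = 8) +
    ggplot2::scale_color_manual(values = palette) +
    ggplot2::scale_fill_manual(values = palette) +
    ggplot2::coord_cartesian(xlim = xlim, ylim = ylim) +
    ggplot2::labs(
      x = "Standardized mean difference (SMD)",
      y = "Relative weight\nMore certain ←   → Less certain"
    ) +
    ggplot2::theme_minimal()
  if (show_cloud) {
    cloud_df <- dplyr::mutate(layout$cloud$dots,
                              y = layout$summary_y + .data$y_offset)
    p <- p + ggplot2::geom_point(data = cloud_df,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 color = "grey25", size = 1.4)
  }
  p +
    ggplot2::annotate("text", x = xlim[1], y = max(ylim), hjust = 0,
                      vjust = 1, label = "Decreased scores",
                      color = palette[["negative"]], size = 3) +
    ggplot2::annotate("text", x = xlim[2], y = max(ylim), hjust = 1,
                      vjust = 1, label = "Increased scores",
                      color = palette[["positive"]], size = 3)
}

#' Plot a MARC layout
#'
#' Static rendering of a [marc_layout()]: v1 on a single vertical scale
#' with the summary cloud at the top (combined weight 1.0); v2 as two
#' panes, the cloud in its own upper pane and the studies rescaled below.
#'
#' @param object A `"marc_layout"`.
#' @param palette Named colors for the `negative`/`positive`/`zero`
#'   diverging classes.
#' @param ... Unused.
#' @return A ggplot (v1) or patchwork (v2) object.
#' @export
autoplot.marc_layout <- function(object, palette = marc_palette(), ...) {
  xlim <- x_range(object)
  if (object$version == "v1") {
    ylim <- c(0, 1.0 + 1.05 * max(abs(object$cloud$dots$y_offset), 0.02))
    return(marc_study_panel(object, xlim, ylim, palette, show_cloud = TRUE) +
             ggplot2::ggtitle("MARC plot (v1)"))
  }
  studies_ylim <- c(0, object$panes$y_max[object$panes$pane == "studies"])
  lower <- marc_study_panel(object, xlim, studies_ylim, palette)
  cloud_df <- object$cloud$dots
  upper <- ggplot2::ggplot(cloud_df,
                           ggplot2::aes(x = .data$x, y = .data$y_offset)) +
    ggplot2::geom_vline(xintercept = object$zero_line, linetype = "dashed",
                        color = "grey40") +
    ggplot2::geom_point(color = "grey25", size = 1.4) +
    ggplot2::coord_cartesian(xlim = xlim) +
    ggplot2::labs(x = NULL, y = "Summary") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_blank())
  patchwork::wrap_plots(upper, lower, ncol = 1,
                        heights = object$panes$height) +
    patchwork::plot_annotation(title = "MARC plot (v2)")
}

#' Plot a forest layout
#'
#' @param object A `"forest_layout"`.
#' @param ... Unused.
#' @return A ggplot object: squares (area proportional to raw weight) with
#'   CI whiskers and a pooled-effect diamond on the bottom row.
#' @export
autoplot.forest_layout <- function(object, ...) {
  d <- object$diamond
  dh <- 0.35
  diamond_df <- tibble::tibble(
    x = c(d$x_left, d$x_center, d$x_right, d$x_center),
    y = c(d$row, d$row + dh, d$row, d$row - dh)
  )
  ggplot2::ggplot() +
    ggplot2::geom_vline(xintercept = object$zero_line, linetype = "dashed",
                        color = "grey40") +
    ggplot2::geom_segment(
      data = object$marks,
      ggplot2::aes(x = .data$ci_low, xend = .data$ci_high,
                   y = .data$y, yend = .data$y),
      color = "grey30"
    ) +
    ggplot2::geom_point(
      data = object$marks,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$area),
      shape = 15, show.legend = FALSE
    ) +
    ggplot2::scale_size_area(max_size = 6) +
    ggplot2::geom_polygon(data = diamond_df,
                          ggplot2::aes(x = .data$x, y = .data$y),
                          fill = "grey20") +
    ggplot2::scale_y_continuous(
      breaks = object$marks$y, labels = object$marks$study_id
    ) +
    ggplot2::labs(x = "Standardized mean difference (SMD)", y = NULL,
                  title = "Forest plot") +
    ggplot2::theme_minimal()
}

#' Plot a bar layout
#'
#' @param object A `"bar_layout"`.
#' @param palette Named colors for the diverging classes.
#' @param ... Unused.
#' @return A ggplot object of horizontal bars from the zero line.
#' @export
autoplot.bar_layout <- function(object, palette = marc_palette(), ...) {
  ggplot2::ggplot() +
    ggplot2::geom_vline(xintercept = object$zero_line, color = "grey40") +
    ggplot2::geom_segment(
      data = object$marks,
      ggplot2::aes(x = 0, xend = .data$x, y = .data$y, yend = .data$y,
                   color = .data$color),
      linewidth = 4, show.legend = FALSE
    ) +
    ggplot2::geom_segment(
      data = object$summary_bar,
      ggplot2::aes(x = 0, xend = .data$x, y = .data$row, yend = .data$row),
      linewidth = 5, color = "grey20"
    ) +
    ggplot2::scale_color_manual(values = palette) +
    ggplot2::scale_y_continuous(
      breaks = c(object$marks$y, 0),
      labels = c(object$marks$study_id, "Summary")
    ) +
    ggplot2::labs(x = "Standardized mean difference (SMD)", y = NULL,
                  title = "Bar plot") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Render a layout to a file
#'
#' Writes a layout as a static image (PNG or SVG via ggplot2) or as a
#' self-contained interactive HTML document in which hovering a mark shows
#' its layout hover text. Rendering never alters layout numbers: the HTML
#' document embeds the layout's mark table verbatim in a JSON data block
#' (`<script type="application/json" id="layout-data">`), and all pixel
#' positions are affine maps of layout coordinates.
#'
#' @param layout A `"marc_layout"`, `"forest_layout"` or `"bar_layout"`.
#' @param path Output file path; the directory must exist and be writable.
#' @param format `"png"`, `"svg"`, or `"html"`; defaults to the file
#'   extension of `path`.
#' @param width,height Device size in inches (static formats).
#' @return `path`, invisibly.
#' @export
render_layout <- function(layout, path,
                          format = c("auto", "png", "svg", "html"),
                          width = 7, height = 5) {
  stopifnot(inherits(layout, "plot_layout"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("png", "svg", "html")) {
      abort("cannot infer format; use `format` or a .png/.svg/.html path.")
    }
  }
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, mode = 2) != 0) {
    abort(paste0("directory not writable: ", dir))
  }
  if (format == "html") {
    writeLines(layout_html(layout), path, useBytes = TRUE)
  } else {
    dev <- if (format == "png") {
      function(filename, ...) grDevices::png(filename, ..., res = 150,
                                             units = "in", type = "cairo")
    } else {
      grDevices::svg
    }
    ggplot2::ggsave(path, plot = ggplot2::autoplot(layout), device = dev,
                    width = width, height = height)
  }
  invisible(path)
}

# ---- interactive HTML -------------------------------------------------

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# Affine map from data to pixel coordinates.
px_scale <- function(domain, range) {
  force(domain); force(range)
  function(v) range[1] + (v - domain[1]) / diff(domain) * diff(range)
}

# Emits an SVG <circle>/<rect> per mark with a <title> child carrying the
# hover text (the standard-HTML tooltip mechanism), plus the cloud and a
# zero line. The full mark/cloud tables are embedded as JSON so that a
# consumer (or a test) can recover the exact layout numbers.
layout_html <- function(layout, width = 760, height = 520) {
  marks <- layout$marks
  xs <- c(marks$x, 0)
  ys <- marks$y
  cloud <- NULL
  if (!is.null(layout$cloud)) {
    cloud <- dplyr::mutate(layout$cloud$dots,
                           y_abs = layout$summary_y + .data$y_offset)
    xs <- c(xs, cloud$x)
  }
  if ("ci_low" %in% names(marks)) xs <- c(xs, marks$ci_low, marks$ci_high)
  xdom <- range(xs) + c(-0.06, 0.06) * diff(range(xs))
  is_marc <- inherits(layout, "marc_layout")
  if (is_marc && layout$version == "v1") {
    ydom <- c(0, 1.0 + max(abs(layout$cloud$dots$y_offset)) * 1.2 + 0.02)
  } else if (is_marc) {
    ydom <- c(0, layout$panes$y_max[layout$panes$pane == "studies"])
  } else {
    ydom <- c(-0.8, layout$n_rows - 1 + 0.8)
  }
  sx <- px_scale(xdom, c(50, width - 15))
  sy <- px_scale(ydom, c(height - 40, 60))
  pal <- marc_palette()
  esc <- function(s) html_escape(s)
  svg <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
            width, height),
    sprintf('<line x1="%.1f" y1="20" x2="%.1f" y2="%d" stroke="#999" stroke-dasharray="4 3"/>',
            sx(0), sx(0), height - 30),
    sprintf('<text x="55" y="30" fill="%s" font-size="12">Decreased scores</text>',
            pal[["negative"]]),
    sprintf('<text x="%d" y="30" fill="%s" font-size="12" text-anchor="end">Increased scores</text>',
            width - 20, pal[["positive"]]),
    sprintf('<text x="15" y="%d" font-size="11" transform="rotate(-90 15 %d)" text-anchor="middle">More certain &#8592;   &#8594; Less certain</text>',
            height %/% 2, height %/% 2)
  )
  max_area <- max(marks$area)
  for (i in seq_len(nrow(marks))) {
    rr <- 3 + 9 * sqrt(marks$area[i] / max_area)  # radius from area share
    svg <- c(svg, sprintf(
      '<circle class="mark" cx="%.2f" cy="%.2f" r="%.2f" fill="%s" fill-opacity="0.85"><title>%s</title></circle>',
      sx(marks$x[i]), sy(marks$y[i]), rr, pal[[marks$color[i]]],
      esc(marks$hover[i])))
  }
  if (!is.null(cloud)) {
    cy <- if (is_marc && layout$version == "v2") {
      # own pane: fixed band above the study pane
      function(off) 40 + off / max(max(abs(cloud$y_offset)), 1e-12) * 14
    } else {
      function(off) sy(layout$summary_y + off)
    }
    hover_cloud <- sprintf("Summary SMD: %.2f\n%g%% CI [%.2f, %.2f]",
                           layout$pooled$estimate, 100 * layout$pooled$level,
                           layout$pooled$ci_low, layout$pooled$ci_high)
    for (i in seq_len(nrow(cloud))) {
      svg <- c(svg, sprintf(
        '<circle class="cloud" cx="%.2f" cy="%.2f" r="2.6" fill="#444"><title>%s</title></circle>',
        sx(cloud$x[i]), cy(cloud$y_offset[i]), esc(hover_cloud)))
    }
  }
  svg <- c(svg, "</svg>")
  payload <- list(
    type = class(layout)[1],
    marks = marks,
    cloud = if (is.null(cloud)) NULL else layout$cloud$dots,
    pooled = unclass(layout$pooled)
  )
  json <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                           null = "null")
  c("<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/>",
    "<title>Meta-analytic visualization</title></head><body>",
    svg,
    sprintf('<script type="application/json" id="layout-data">%s</script>',
            json),
    "</body></html>")
}
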