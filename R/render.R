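# Rendering: a thin ggplot2 layer over the plot-data tables.

plot_base <- function(pd, ylab) {
  bd <- pd$axis$boundaries
  ggplot2::ggplot() +
    ggplot2::geom_vline(
      xintercept = bd$end, linewidth = 0.2, colour = "grey70"
    ) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey40") +
    ggplot2::scale_x_continuous(
      breaks = bd$mid, labels = bd$chrom, expand = c(0.01, 0)
    ) +
    ggplot2::labs(x = "chromosome", y = ylab) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
}

#' Build the ggplot for a plot-data object
#'
#' @param pd A `cnv_plot_data` from one of the four builders.
#' @return A ggplot object.
#' @export
cnv_ggplot <- function(pd) {
  switch(pd$kind,
    cs_intensity = {
      g <- plot_base(pd, "mean log2 ratio") +
        ggplot2::geom_point(
          data = pd$points, ggplot2::aes(x = .data$x, y = .data$value),
          size = 0.3, alpha = 0.4, colour = "grey35"
        ) +
        ggplot2::geom_segment(
          data = pd$segments,
          ggplot2::aes(
            x = .data$x_start, xend = .data$x_end,
            y = .data$value, yend = .data$value
          ),
          colour = "firebrick", linewidth = 0.9
        )
      if (nrow(pd$labels)) {
        g <- g + ggplot2::geom_text(
          data = pd$labels,
          ggplot2::aes(x = .data$x, y = .data$value, label = .data$gene),
          vjust = -0.8, size = 2.8
        )
      }
      g
    },
    sw_intensity = plot_base(pd, "segment log2 ratio") +
      ggplot2::geom_rect(
        data = pd$rects,
        ggplot2::aes(
          xmin = .data$x_start, xmax = .data$x_end,
          ymin = .data$value - 0.02, ymax = .data$value + 0.02
        ),
        alpha = pd$rects$opacity[1], fill = "navy"
      ),
    cs_frequency = ,
    sw_frequency = plot_base(pd, "aberration frequency") +
      ggplot2::geom_rect(
        data = pd$bars,
        ggplot2::aes(
          xmin = .data$x_start, xmax = .data$x_end, ymin = 0, ymax = .data$gain
        ),
        fill = "firebrick"
      ) +
      ggplot2::geom_rect(
        data = pd$bars,
        ggplot2::aes(
          xmin = .data$x_start, xmax = .data$x_end, ymin = .data$loss, ymax = 0
        ),
        fill = "steelblue"
      ) +
      ggplot2::coord_cartesian(ylim = c(-1, 1)),
    stop_fmt("unknown plot kind: %s", pd$kind)
  )
}

#' Render a plot-data object to a figure file
#'
#' @param pd A `cnv_plot_data`.
#' @param path Output file path.
#' @param format One of `"pdf"`, `"png"`, `"svg"` (default from the file
#'   extension).
#' @param width,height Figure size in inches.
#' @return Invisibly, `path`.
#' @export
render_cnv_plot <- function(pd, path, format = NULL,
                            width = 10, height = 3.5) {
  format <- format %||% tolower(tools::file_ext(path))
  if (!format %in% c("pdf", "png", "svg")) {
    stop_fmt("unsupported figure format: %s", format)
  }
  dev <- switch(format,
    pdf = function(p) grDevices::pdf(p, width = width, height = height),
    png = function(p) {
      grDevices::png(p, width = width * 100, height = height * 100, res = 100)
    },
    svg = function(p) grDevices::svg(p, width = width, height = height)
  )
  dev(path)
  on.exit(grDevices::dev.off())
  print(cnv_ggplot(pd))
  invisible(path)
}
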