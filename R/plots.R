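# Manhattan and QQ figures.

#' Manhattan plot of gene-level association results
#'
#' @param results Results data.frame (see [manhattan_data()]).
#' @param alpha Significance level for the Bonferroni line.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(results, alpha = 0.05) {
  md <- manhattan_data(results, alpha)
  thr <- attr(md, "threshold_line")
  ggplot2::ggplot(md, ggplot2::aes(x = x, y = y, colour = factor(color_index))) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                        colour = "red") +
    ggplot2::scale_colour_manual(values = c("grey30", "steelblue")) +
    ggplot2::labs(x = "genome position", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' QQ plot of gene-level p-values
#'
#' @param p_values Numeric vector of p-values.
#' @return A ggplot object with the lambda GC estimate in the subtitle.
#' @export
plot_qq <- function(p_values) {
  qd <- qq_data(p_values)
  lgc <- lambda_gc(p_values)
  ggplot2::ggplot(qd, ggplot2::aes(x = expected, y = observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(expected ~ -log[10](p)),
                  y = expression(observed ~ -log[10](p)),
                  subtitle = sprintf("lambda[GC] = %.3f", lgc)) +
    ggplot2::theme_minimal()
}

#' Save a plot as PNG and SVG
#'
#' @param plot A ggplot object.
#' @param dir Output directory (created if needed).
#' @param name Base file name without extension.
#' @param width,height Size in inches.
#' @return Invisibly, the written paths.
#' @export
save_plot_files <- function(plot, dir, name, width = 8, height = 4.5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(name, c(".png", ".svg")))
  ggplot2::ggsave(paths[1], plot, width = width, height = height, dpi = 150)
  # the base svg device avoids an svglite dependency
  ggplot2::ggsave(paths[2], plot, width = width, height = height,
                  device = grDevices::svg)
  invisible(paths)
}
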