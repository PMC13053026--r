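need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
}

#' Violin plot of stability distances by condition
#'
#' Diagnostic view of production stability: violins with overlaid boxplots
#' and the condition mean marked in red.
#'
#' @param stability A [stability_observations()] tibble.
#' @return A ggplot object.
#' @export
plot_stability <- function(stability) {
  need_ggplot()
  ggplot2::ggplot(stability,
                  ggplot2::aes(x = .data$condition, y = .data$distance)) +
    ggplot2::geom_violin() +
    ggplot2::geom_boxplot(width = 0.12, outlier.shape = NA) +
    ggplot2::stat_summary(fun = mean, geom = "point", color = "red") +
    ggplot2::labs(x = "condition", y = "distance between successive signals")
}

#' Violin plot of success indices by condition
#'
#' @param per_dyad A [per_dyad_summary()] tibble.
#' @param dv Column to plot.
#' @return A ggplot object.
#' @export
plot_success <- function(per_dyad, dv = "success_index") {
  need_ggplot()
  ggplot2::ggplot(per_dyad,
                  ggplot2::aes(x = .data$condition, y = .data[[dv]])) +
    ggplot2::geom_violin() +
    ggplot2::geom_boxplot(width = 0.12, outlier.shape = NA) +
    ggplot2::stat_summary(fun = mean, geom = "point", color = "red") +
    ggplot2::labs(x = "condition", y = dv)
}

#' Render the pad colorspace as a raster plot
#'
#' @param n Grid resolution per axis.
#' @return A ggplot object.
#' @export
plot_colorspace <- function(n = 64) {
  need_ggplot()
  g <- colorspace_grid(n)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$u, y = .data$v,
                                  fill = .data$hex)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_identity() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "u (pad x)", y = "v (pad y, bottom = 0)")
}
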