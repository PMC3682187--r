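# ggplot2 front-ends for the main result types.

#' @export
autoplot.metagene_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$offset_mid, y = .data$mean_signal)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(
      x = sprintf("distance from %s (bp, 5'→3')", attr(object, "anchor")),
      y = "mean tag density (per Mb tags per bp)",
      title = sprintf("%s metagene profile (%d genes)",
                      attr(object, "marker") %||% "", object$n_genes[1])) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.marker_threshold <- function(object, bins = 60, ...) {
  df <- tibble(x = object$values)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey50") +
    ggplot2::geom_vline(xintercept = object$tau, colour = "#d7301f",
                        linewidth = 0.8) +
    ggplot2::labs(x = "log10 enrichment", y = "density",
                  title = sprintf("threshold fit (%s), tau = %.3f",
                                  object$method, object$tau)) +
    ggplot2::theme_minimal()
  if (identical(object$method, "mixture")) {
    grid <- seq(min(df$x), max(df$x), length.out = 400)
    comp <- dplyr::bind_rows(
      tibble(x = grid, component = "background",
             density = object$lambda[1] * dnorm(grid, object$mu[1], object$sigma[1])),
      tibble(x = grid, component = "signal",
             density = object$lambda[2] * dnorm(grid, object$mu[2], object$sigma[2])))
    p <- p + ggplot2::geom_line(
      data = comp,
      ggplot2::aes(x = .data$x, y = .data$density, colour = .data$component)) +
      ggplot2::scale_colour_manual(values = c(background = "#636363",
                                              signal = "#2c7fb8"))
  }
  p
}

#' @export
autoplot.group_assignment <- function(object, ...) {
  counts <- dplyr::count(as_tibble(object), .data$group, name = "n_genes")
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$group, y = .data$n_genes,
                                       fill = .data$group)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "chromatin-state group sizes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
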