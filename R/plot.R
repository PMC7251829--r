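# ggplot2 visualizations.

#' Plot a per-read BrdU content profile with its detected tracks
#'
#' @param profile Profile tibble of one read (`position`, `value`).
#' @param tracks Optional track tibble for the same read.
#' @param events Optional event tibble for the same read.
#' @return A ggplot object.
#' @export
plot_read_profile <- function(profile, tracks = NULL, events = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$position / 1000,
                                             y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey30") +
    ggplot2::labs(x = "position (kb)", y = "BrdU content",
                  title = unique(profile$read_id)[1]) +
    ggplot2::theme_minimal()
  if (!is.null(tracks) && nrow(tracks)) {
    p <- p + ggplot2::geom_segment(
      data = tracks,
      ggplot2::aes(x = .data$start / 1000, xend = .data$end / 1000,
                   colour = .data$orientation),
      y = -0.05, yend = -0.05, linewidth = 2, inherit.aes = FALSE,
      arrow = ggplot2::arrow(length = ggplot2::unit(4, "pt")))
  }
  if (!is.null(events) && nrow(events)) {
    p <- p + ggplot2::geom_vline(
      data = events,
      ggplot2::aes(xintercept = .data$midpoint / 1000,
                   linetype = .data$type), colour = "red")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a genome signal track
#'
#' @param object A `genome_signal`.
#' @param chrom Optional chromosome subset.
#' @param ... Unused.
#' @return A ggplot object, faceted by chromosome.
#' @export
autoplot.genome_signal <- function(object, chrom = NULL, ...) {
  d <- if (is.null(chrom)) object else object[object$chrom %in% chrom, ]
  ggplot2::ggplot(d, ggplot2::aes(x = (.data$start + .data$end) / 2000,
                                  y = .data$value)) +
    ggplot2::geom_line(na.rm = TRUE, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (kb)", y = attr(object, "kind")) +
    ggplot2::theme_minimal()
}

#' Plot cluster counts against the clustering limit
#'
#' @param sweep Tibble from [cluster_sweep()].
#' @return A ggplot object.
#' @export
plot_cluster_sweep <- function(sweep) {
  d <- tidyr::pivot_longer(sweep[, c("mied", "n_singleton", "n_multi")],
                           -"mied", names_to = "class", values_to = "n")
  d$class <- ifelse(d$class == "n_singleton", "d = 1", "d > 1")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mied / 1000, y = .data$n,
                                  colour = .data$class)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "clustering limit mIED (kb)", y = "clusters") +
    ggplot2::theme_minimal()
}

#' Plot the training history of the convolutional estimator
#'
#' @param object A `brdu_cnn`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.brdu_cnn <- function(object, ...) {
  d <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "set", values_to = "loss")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~pass, labeller = ggplot2::label_both) +
    ggplot2::labs(y = "mean squared error") +
    ggplot2::theme_minimal()
}
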