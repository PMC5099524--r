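#' Barcode plot
#'
#' Horizontal persistence intervals, one per H1 class, from birth to death
#' step; open classes are drawn to the end of the filtration with an arrow
#' cue (dashed).
#'
#' @param object an `hs_barcode`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.hs_barcode <- function(object, ...) {
  n_steps <- attr(object, "n_steps")
  td <- tidy(object)
  td$end <- ifelse(is.na(td$death), n_steps + 0.5, td$death)
  ggplot2::ggplot(td, ggplot2::aes(y = factor(.data$id))) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$birth, xend = .data$end,
                                       yend = factor(.data$id),
                                       linetype = .data$open),
                          linewidth = 1.2, show.legend = FALSE) +
    ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid",
                                              `TRUE` = "dashed")) +
    ggplot2::scale_x_continuous(breaks = seq_len(n_steps)) +
    ggplot2::labs(x = "filtration step", y = "H1 class",
                  title = "Persistence barcode (H1)")
}

#' Scaffold edge-weight heatmap
#'
#' @param object an `hs_scaffold`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.hs_scaffold <- function(object, ...) {
  df <- as.data.frame(as.table(object$H))
  names(df) <- c("from", "to", "weight")
  ggplot2::ggplot(df, ggplot2::aes(.data$from, .data$to,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = paste(object$variant, "scaffold"),
                  x = NULL, y = NULL)
}

#' Threshold-sweep curves
#'
#' One line per node, faceted by metric, value against link density.
#'
#' @param object an `hs_sweep`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.hs_sweep <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(.data$density, .data$value,
                               group = .data$node)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "link density", y = "metric value",
                  title = "Binary metrics across the density grid")
}

#' Correlation-versus-density profile of a full analysis
#'
#' Correlation coefficient of each metric pair across the density grid;
#' filled points mark correlations significant at p < 0.05.
#'
#' @param object an `hs_analysis`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.hs_analysis <- function(object, ...) {
  pd <- object$correlations[!is.na(object$correlations$density), ]
  ggplot2::ggplot(pd, ggplot2::aes(.data$density, .data$r,
                                   colour = .data$pair)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(alpha = .data$significant),
                        show.legend = c(alpha = FALSE)) +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.25, `TRUE` = 1)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "link density", y = "Pearson R",
                  title = "Metric-metric correlations across thresholds")
}
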