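#' Plot a construct map
#'
#' Linearized feature map of an assembled plasmid: one coloured block per
#' brick in grammar order, junction letters marked at the block boundaries.
#'
#' @param object A `gg_construct`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gg_construct
#' @export
autoplot.gg_construct <- function(object, ...) {
  feats <- object$features
  ggplot2::ggplot(feats) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start, xmax = .data$end, ymin = 0, ymax = 1,
      fill = .data$category), colour = "grey20", linewidth = 0.2) +
    ggplot2::geom_text(ggplot2::aes(
      x = (.data$start + .data$end) / 2, y = 0.5, label = .data$name),
      size = 3, angle = 90) +
    ggplot2::geom_text(data = object$junctions, ggplot2::aes(
      x = .data$position, y = 1.15, label = .data$letter), size = 3) +
    ggplot2::scale_y_continuous(NULL, breaks = NULL, limits = c(-0.2, 1.3)) +
    ggplot2::labs(x = "position (bp)", fill = NULL,
      title = sprintf("%s (%d bp, circular)", object$plasmid$name,
        length(object$plasmid))) +
    ggplot2::theme_minimal()
}

#' Plot a digest gel prediction
#'
#' Pseudo-gel of fragment sizes from a [digest()] result (log-scaled
#' migration, one lane).
#'
#' @param object A `gg_digest` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gg_digest
#' @export
autoplot.gg_digest <- function(object, ...) {
  d <- tibble::tibble(length = sort(object$length, decreasing = TRUE))
  ggplot2::ggplot(d, ggplot2::aes(x = 1, y = .data$length)) +
    ggplot2::geom_tile(width = 0.5, height = 0.02 * d$length, fill = "grey20") +
    ggplot2::scale_y_log10("fragment size (bp)") +
    ggplot2::scale_x_continuous(NULL, breaks = NULL) +
    ggplot2::labs(title = sprintf("%d fragment(s)", nrow(d))) +
    ggplot2::theme_minimal()
}
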