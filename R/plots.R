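#' Plot a similarity trajectory
#'
#' One line per semantic pointer: the similarity of the buffer's decoded
#' state direction with each vocabulary entry over time, the standard way of
#' visualising buffer contents.
#'
#' @param object a [decode_similarities()] tibble.
#' @param top_n label only the `top_n` pointers with the largest peak
#'   similarity; the rest are drawn in grey.
#' @param ... unused.
#' @method autoplot spa_similarity
#' @export
autoplot.spa_similarity <- function(object, top_n = 8, ...) {
  plot_similarity(object, top_n = top_n)
}

#' @rdname autoplot.spa_similarity
#' @param sims a [decode_similarities()] tibble.
#' @export
plot_similarity <- function(sims, top_n = 8) {
  long <- tidyr::pivot_longer(sims, -"time",
                              names_to = "pointer", values_to = "similarity")
  peaks <- dplyr::slice_max(
    dplyr::summarise(dplyr::group_by(long, .data$pointer),
                     peak = max(abs(.data$similarity)), .groups = "drop"),
    .data$peak, n = top_n)
  long$pointer_lab <- ifelse(long$pointer %in% peaks$pointer,
                             long$pointer, "other")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$similarity,
                                     group = .data$pointer,
                                     colour = .data$pointer_lab)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_colour_manual(
      values = c(stats::setNames(
        scales_hue(length(peaks$pointer)), peaks$pointer), other = "grey80"),
      name = NULL) +
    ggplot2::labs(x = "time (s)", y = "similarity") +
    ggplot2::theme_minimal()
}

scales_hue <- function(n) {
  grDevices::hcl(h = seq(15, 375, length.out = n + 1)[-(n + 1)], c = 100, l = 55)
}

#' Plot a performance-versus-ablation curve
#'
#' Per-fraction mean correct-item count with the min-max range of the
#' repeats, the standard lesion-response summary.
#'
#' @param object an [run_sweep()] result.
#' @param ... unused.
#' @method autoplot ablation_sweep
#' @export
autoplot.ablation_sweep <- function(object, ...) {
  tt <- tidy.ablation_sweep(object)
  ggplot2::ggplot(tt, ggplot2::aes(100 * .data$fraction, .data$mean_correct)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min_correct,
                                      ymax = .data$max_correct),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "ablated neurons (%)", y = "correct items",
      title = sprintf("%s: ablation of %s", attr(object, "task"),
                      attr(object, "target"))
    ) +
    ggplot2::theme_minimal()
}
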