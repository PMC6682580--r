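#' Plot a 2D embedding of variability vectors
#'
#' Scatter of compounds in the embedded plane, coloured by activity class
#' with the red/black convention for actives/inactives.
#'
#' @param object A [embed_vectors()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pose_embedding
#' @export
autoplot.pose_embedding <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$x, .data$y,
                                              colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(active = "red", inactive = "black"),
      na.value = "grey60", drop = FALSE) +
    ggplot2::labs(x = paste0(object$method, " 1"),
                  y = paste0(object$method, " 2"),
                  colour = "activity") +
    ggplot2::theme_minimal()
}

#' Plot pose-consistency results
#'
#' Descriptor variability against rotatable-bond count, one panel per
#' ensemble depth `k`, with a linear trend line — the visual counterpart of
#' [rotbond_correlation()].
#'
#' @param object A [pose_consistency()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pose_consistency
#' @export
autoplot.pose_consistency <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$n_rot, .data$descriptor_std)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label), alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::scale_colour_manual(
      values = c(active = "red", inactive = "black"),
      na.value = "grey60", drop = FALSE) +
    ggplot2::facet_wrap(~k, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "rotatable bonds",
                  y = "mean descriptor std (standardized)",
                  colour = "activity") +
    ggplot2::theme_minimal()
}

#' Plot the per-descriptor variability ranking
#'
#' Dot plot of mean per-compound std for the most and least stable
#' descriptors.
#'
#' @param summary_tbl Output of [per_descriptor_std_summary()].
#' @param n_each How many descriptors to show from each end of the ranking.
#' @return A ggplot object.
#' @export
plot_descriptor_ranking <- function(summary_tbl, n_each = 15) {
  shown <- dplyr::bind_rows(utils::head(summary_tbl, n_each),
                            utils::tail(summary_tbl, n_each)) |>
    dplyr::distinct() |>
    dplyr::mutate(descriptor = factor(.data$descriptor,
                                      levels = .data$descriptor))
  ggplot2::ggplot(shown, ggplot2::aes(.data$mean_std, .data$descriptor)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "mean per-compound std (standardized)", y = NULL) +
    ggplot2::theme_minimal()
}
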