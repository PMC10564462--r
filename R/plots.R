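#' Plot decoding results
#'
#' Time courses are drawn as lines (one per train/test variable-subset
#' combination); time-time generalization results as a raster.
#'
#' @param object a `cvm_decoding` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cvm_decoding <- function(object, ...) {
  d <- dplyr::mutate(as_tibble(object),
                     label = paste0(.data$variable_train, "[",
                                    .data$subset_train, "] → ",
                                    .data$variable_test, "[",
                                    .data$subset_test, "]"))
  if (all(abs(d$t_train - d$t_test) < 1e-9)) {
    ggplot2::ggplot(d, ggplot2::aes(.data$t_train, .data$D,
                                    colour = .data$label)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 3) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (s)", y = "pattern distinctness D",
                    colour = NULL) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(.data$t_train, .data$t_test,
                                    fill = .data$D)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_gradient2() +
      ggplot2::labs(x = "train time (s)", y = "test time (s)") +
      ggplot2::coord_equal() +
      ggplot2::theme_minimal()
  }
}

#' Plot region-averaged searchlight time courses
#'
#' @param group_courses a [group_average()] tibble.
#' @return A ggplot object.
#' @export
plot_group_info <- function(group_courses) {
  ggplot2::ggplot(group_courses,
                  ggplot2::aes(.data$t, .data$D_norm, colour = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "normalized distinctness",
                  colour = "region") +
    ggplot2::theme_minimal()
}

#' Plot a reconstructed representational geometry
#'
#' Draws the condition-difference vectors of [reconstruct_geometry()] from
#' the origin, annotated with the angle between them.
#'
#' @param object a `cvm_geometry` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cvm_geometry <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(
      ggplot2::aes(x = 0, y = 0, xend = .data$x, yend = .data$y,
                   colour = .data$variable),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "inches"))) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(sqrt(D)), y = NULL, colour = NULL,
                  subtitle = sprintf("angle = %.1f°",
                                     max(d$angle_deg))) +
    ggplot2::theme_minimal()
}
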