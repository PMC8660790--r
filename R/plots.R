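#' Plot an estimated network
#'
#' Circular-layout diagram of the significant links: straight segments for
#' contemporaneous associations, curved for lagged, green for positive and
#' red for negative weights, line width scaled by |weight|. Self-links are
#' omitted.
#'
#' @param object An `ema_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ema_network <- function(object, ...) {
  vars <- object$variable_names
  n <- length(vars)
  theta <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  layout <- tibble::tibble(name = vars, x = cos(theta), y = sin(theta))
  links <- object$links[object$links$source != object$links$target, ,
                        drop = FALSE]
  if (nrow(links) == 0) {
    return(
      ggplot2::ggplot(layout, ggplot2::aes(.data$x, .data$y)) +
        ggplot2::geom_label(ggplot2::aes(label = .data$name)) +
        ggplot2::coord_equal() + ggplot2::theme_void()
    )
  }
  seg <- links |>
    dplyr::left_join(layout, by = c(source = "name")) |>
    dplyr::left_join(layout, by = c(target = "name"),
                     suffix = c("", "end")) |>
    dplyr::mutate(
      channel = ifelse(.data$lag == 0, "contemporaneous", "lagged"),
      sign = ifelse(.data$weight > 0, "positive", "negative")
    )
  ggplot2::ggplot() +
    ggplot2::geom_curve(
      data = seg[seg$channel == "lagged", ],
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$sign,
                   linewidth = abs(.data$weight)),
      curvature = 0.25,
      arrow = ggplot2::arrow(length = ggplot2::unit(2.5, "mm"))
    ) +
    ggplot2::geom_segment(
      data = seg[seg$channel == "contemporaneous", ],
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$sign,
                   linewidth = abs(.data$weight))
    ) +
    ggplot2::geom_label(data = layout,
                        ggplot2::aes(.data$x, .data$y, label = .data$name)) +
    ggplot2::scale_colour_manual(
      values = c(positive = "#1a9850", negative = "#d73027")
    ) +
    ggplot2::scale_linewidth(range = c(0.3, 1.6), guide = "none") +
    ggplot2::coord_equal(clip = "off") +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL)
}

#' Plot a two-group run report
#'
#' Side-by-side link-density bars per group (count and weight modes) with
#' the between-group R-squared in the subtitle.
#'
#' @param object An `ema_run_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ema_run_report <- function(object, ...) {
  dens <- object$metrics$density |>
    tidyr::pivot_longer(c("density_count", "density_weight"),
                        names_to = "mode", values_to = "density") |>
    dplyr::mutate(mode = sub("density_", "", .data$mode))
  subtitle <- if (nrow(object$metrics$r2) > 0) {
    sprintf("network R² (%s vs %s) = %.2f",
            object$metrics$r2$network_a[1], object$metrics$r2$network_b[1],
            object$metrics$r2$r2[1])
  } else NULL
  ggplot2::ggplot(dens, ggplot2::aes(.data$network, .data$density,
                                     fill = .data$mode)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "network density", subtitle = subtitle) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
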