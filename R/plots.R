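#' @method autoplot sfc_coupling_matrix
#' @export
autoplot.sfc_coupling_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target, y = .data$source,
                                   fill = .data$coupling)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "FC subject", y = "source subject",
      title = sprintf("Cross-participant coupling (%s)", attr(object, "approach")),
      fill = "r"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot sfc_decomposition
#' @export
autoplot.sfc_decomposition <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("matched", "mismatched"),
                        names_to = "kind", values_to = "coupling")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kind, y = .data$coupling)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject), alpha = 0.25) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(
      x = NULL, y = "structure-function coupling",
      title = sprintf("Matched vs mismatched coupling (t = %.2f, p = %.2g)",
                      object$t_statistic, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Regional effect map against the cortical axis
#'
#' Scatter of a regional effect (group, individual, ...) against axis rank,
#' with a linear trend; points outside `mean +/- 3 sd` are flagged.
#'
#' @param regional Tibble from [regional_effect_maps()] (or the `regional`
#'   element of an `sfc_report`), filtered to one approach.
#' @param region_meta Region metadata with `axis_rank`.
#' @param effect Column to plot (default `"individual"`).
#' @return A ggplot object.
#' @export
plot_axis_effect <- function(regional, region_meta, effect = "individual") {
  df <- dplyr::left_join(regional, region_meta, by = "region_id")
  df$value <- df[[effect]]
  df$outlier <- !outlier_mask(df$value)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$axis_rank, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$axis_rank,
                                     shape = .data$outlier)) +
    ggplot2::geom_smooth(data = ~ dplyr::filter(.x, !.data$outlier),
                         method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey30") +
    ggplot2::scale_colour_viridis_c(option = "plasma") +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4), guide = "none") +
    ggplot2::labs(x = "sensorimotor-association axis rank", y = effect,
                  colour = "rank") +
    ggplot2::theme_minimal()
}
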