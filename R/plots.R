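#' Plot a fitted trajectory over its observations
#'
#' @param object A [fit_trajectory()] result.
#' @param ... Unused.
#' @return A ggplot: observed series as points, fitted piecewise-linear
#'   trajectory as a line, vertices marked.
#' @method autoplot segment_fit
#' @export
autoplot.segment_fit <- function(object, ...) {
  obs <- tibble::tibble(year = object$years, value = object$series,
                        fitted = object$fitted)
  verts <- tibble::tibble(year = object$vertex_years,
                          value = object$vertex_values)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value), colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#2c7fb8") +
    ggplot2::geom_point(data = verts,
                        ggplot2::aes(y = .data$value),
                        colour = "#d95f02", size = 2) +
    ggplot2::labs(x = "year", y = "index",
                  title = "Temporal segmentation") +
    ggplot2::theme_minimal()
}

#' Map a categorical change result
#'
#' @param object A `change_map`.
#' @param ... Unused.
#' @return A ggplot raster of none/loss/gain labels.
#' @method autoplot change_map
#' @export
autoplot.change_map <- function(object, ...) {
  df <- as_tibble.change_map(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(none = "grey90", loss = "#d7301f",
                                          gain = "#2ca25f")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Map an agreement count
#'
#' @param object An `agreement_map`.
#' @param ... Unused.
#' @return A ggplot raster of per-pixel dataset agreement counts.
#' @method autoplot agreement_map
#' @export
autoplot.agreement_map <- function(object, ...) {
  df <- as_tibble.agreement_map(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = factor(.data$count))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_brewer(palette = "YlOrRd") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = sprintf("datasets\n(%s)", object$direction)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a dataset correlation matrix
#'
#' Insignificant cells (at the matrix's own alpha) are greyed out.
#'
#' @param object A `cor_matrix`.
#' @param ... Unused.
#' @return A ggplot tile map of pairwise r.
#' @method autoplot cor_matrix
#' @export
autoplot.cor_matrix <- function(object, ...) {
  df <- tidy.cor_matrix(object)
  df$fill <- ifelse(df$significant, df$r, NA_real_)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dataset1, y = .data$dataset2)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$fill), colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", limits = c(-1, 1),
                                  na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = sprintf("r (p < %.2f)", object$alpha)) +
    ggplot2::theme_minimal()
}

#' Plot a detector-parameter sweep
#'
#' @param sweep Tibble from [sweep_detector_params()].
#' @param param_name Axis label for the swept parameter.
#' @return A ggplot of loss/gain coverage percent against the parameter.
#' @export
plot_sweep <- function(sweep, param_name = "parameter value") {
  df <- sweep |>
    tidyr::pivot_longer(cols = c("loss_pct", "gain_pct"),
                        names_to = "direction", values_to = "pct") |>
    dplyr::mutate(direction = sub("_pct$", "", .data$direction))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$pct,
                                   colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(loss = "#d7301f",
                                            gain = "#2ca25f")) +
    ggplot2::labs(x = param_name, y = "coverage change (%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
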