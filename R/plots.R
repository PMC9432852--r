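# ggplot2 graphics for the package's result types.

#' Plot a raster layer
#'
#' @param object An `sdm_layer`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sdm_layer
#' @export
autoplot.sdm_layer <- function(object, ...) {
  df <- layer_to_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$longitude, .data$latitude,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude", y = "Latitude")
}

#' Plot a Boyce curve
#'
#' Predicted-to-expected ratio against window midpoint suitability; a
#' monotone increasing curve indicates good calibration.
#'
#' @param object A `boyce_curve` from [cbi()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot boyce_curve
#' @export
autoplot.boyce_curve <- function(object, ...) {
  ggplot2::ggplot(object$windows, ggplot2::aes(.data$midpoint, .data$F)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "Suitability (window midpoint)",
                  y = "Predicted / expected ratio",
                  title = sprintf("Continuous Boyce Index = %.3f", object$cbi))
}

#' Plot a habitat classification
#'
#' @param object A `habitat_classification`.
#' @param ... Unused.
#' @return A ggplot with one fill level per habitat class.
#' @method autoplot habitat_classification
#' @export
autoplot.habitat_classification <- function(object, ...) {
  df <- layer_to_tibble(object$class_layer)
  labels <- object$class_areas$label
  df$class <- factor(labels[df$value], levels = labels)
  ggplot2::ggplot(df, ggplot2::aes(.data$longitude, .data$latitude,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_brewer(palette = "YlGn") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = "Habitat")
}

#' Plot a delineated reserve
#'
#' @param object A `reserve_map`.
#' @param ... Unused.
#' @return A ggplot of core cells.
#' @method autoplot reserve_map
#' @export
autoplot.reserve_map <- function(object, ...) {
  df <- layer_to_tibble(object$core_layer)
  df$core <- df$value > 0
  ggplot2::ggplot(df, ggplot2::aes(.data$longitude, .data$latitude,
                                   fill = .data$core)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey90",
                                          `TRUE` = "darkgreen")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = "Core reserve",
                  title = sprintf("Core reserve: %.1f km2", object$area_km2))
}

#' Plot habitat change trends across scenarios
#'
#' @param trends Long tibble (`species`, `scenario`, `period`, `class`,
#'   `r`) as produced by [run_pipeline()].
#' @return A ggplot faceted by species, change ratio vs period.
#' @export
plot_change_trends <- function(trends) {
  ggplot2::ggplot(trends,
                  ggplot2::aes(.data$period, .data$r, colour = .data$class,
                               group = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::facet_grid(ggplot2::vars(.data$species),
                        ggplot2::vars(.data$scenario)) +
    ggplot2::labs(x = "Period", y = "Relative area change",
                  colour = "Habitat class") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot permutation importances
#'
#' @param importance Tibble from [permutation_importance()].
#' @return A ggplot bar chart.
#' @export
plot_importance <- function(importance) {
  ggplot2::ggplot(importance,
                  ggplot2::aes(stats::reorder(.data$covariate, .data$importance),
                               .data$importance)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Permutation importance (%)")
}
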