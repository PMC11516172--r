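#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_col coord_equal
#'   scale_fill_viridis_c scale_fill_manual labs theme_minimal coord_flip
NULL

#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance

#' Plot a raster grid
#'
#' Continuous grids are drawn with a viridis fill; categorical grids (those
#' carrying a legend) with a discrete fill keyed by class name.
#'
#' @param object A `raster_grid`.
#' @param title Optional plot title.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.raster_grid <- function(object, title = NULL, ...) {
  d <- as_tibble(object)
  p <- if (!is.null(object$legend)) {
    ggplot(d, aes(x = .data$x, y = .data$y, fill = .data$class)) +
      geom_raster() +
      labs(fill = "class")
  } else {
    ggplot(d, aes(x = .data$x, y = .data$y, fill = .data$value)) +
      geom_raster() +
      scale_fill_viridis_c() +
      labs(fill = "value")
  }
  p + coord_equal() + theme_minimal() + labs(title = title, x = "x (m)", y = "y (m)")
}

#' Plot a between-season change surface
#'
#' @param object A `seasonal_change_map` from [change_index()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.seasonal_change_map <- function(object, ...) {
  autoplot(object$index, title = paste("Seasonal change:", object$season_pair)) +
    labs(fill = "change\nindex")
}

#' Plot the GAP overlap classes
#'
#' Uses the conventional color semantics: red for habitat at fire risk,
#' blue for fire risk outside habitat, green for habitat outside fire risk,
#' grey for neither.
#'
#' @param object A `gap_overlap` from [gap_overlap()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gap_overlap <- function(object, ...) {
  d <- as_tibble(object$class_map)
  cols <- c(
    at_risk_habitat = "#d7301f", fire_only = "#2b8cbe",
    habitat_only = "#31a354", neither = "grey85"
  )
  ggplot(d, aes(x = .data$x, y = .data$y, fill = .data$class)) +
    geom_raster() +
    scale_fill_manual(values = cols) +
    coord_equal() +
    theme_minimal() +
    labs(title = "Habitat x wildfire-risk overlap", fill = NULL,
         x = "x (m)", y = "y (m)")
}

#' Plot a variable-importance table
#'
#' @param object An `importance_table` from [variable_importance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.importance_table <- function(object, ...) {
  d <- object
  d$variable <- factor(d$variable, levels = rev(unique(d$variable)))
  ggplot(d, aes(x = .data$variable, y = .data$weight)) +
    geom_col(fill = "#d7301f") +
    coord_flip() +
    theme_minimal() +
    labs(title = "Permutation variable importance", x = NULL, y = "weight")
}

#' Plot member AUCs and weights of a classifier ensemble
#'
#' @param object A `classifier_ensemble` from [fit_suite()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.classifier_ensemble <- function(object, ...) {
  d <- tidy(object)
  d <- tidyr::pivot_longer(d, c("auc", "weight"),
                           names_to = "metric", values_to = "value")
  ggplot(d, aes(x = .data$learner, y = .data$value, fill = .data$metric)) +
    geom_col(position = "dodge") +
    theme_minimal() +
    labs(title = paste0("Ensemble members (", object$registry, ")"),
         x = NULL, y = NULL, fill = NULL)
}
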