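#' Plot a free-energy surface
#'
#' 2D surfaces are drawn as a filled raster with contour lines (1 kcal
#' mol^-1 by default); 1D profiles as a line.
#'
#' @param object A [free_energy_surface()].
#' @param contour_by Contour spacing in kcal mol^-1 (2D only).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot free_energy_surface
#' @export
autoplot.free_energy_surface <- function(object, contour_by = 1, ...) {
  df <- tidy(object)
  if (object$dim == 2L) {
    ggplot2::ggplot(df[!df$masked, ],
                    ggplot2::aes(.data$center_x, .data$center_y)) +
      ggplot2::geom_raster(ggplot2::aes(fill = .data$A)) +
      ggplot2::geom_contour(ggplot2::aes(z = .data$A),
                            binwidth = contour_by, colour = "white",
                            linewidth = 0.2) +
      ggplot2::scale_fill_viridis_c(name = "A (kcal/mol)") +
      ggplot2::labs(x = "coordinate x", y = "coordinate y") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df[!df$masked, ],
                    ggplot2::aes(.data$center_x, .data$A)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "coordinate", y = "A (kcal/mol)") +
      ggplot2::theme_minimal()
  }
}

#' Plot a reaction path profile
#'
#' Free energy along the minimax path with the transition state marked.
#'
#' @param object A `reaction_path` from [minimax_path()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot reaction_path
#' @export
autoplot.reaction_path <- function(object, ...) {
  ts <- attr(object, "ts_index")
  ggplot2::ggplot(object, ggplot2::aes(.data$position, .data$A)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object[ts, ], colour = "red", size = 2) +
    ggplot2::labs(x = "path position", y = "A (kcal/mol)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.free_energy_surface
#' @method autoplot wham_result
#' @export
autoplot.wham_result <- function(object, ...) autoplot(object$fes, ...)

#' Plot two-state trajectory time series
#'
#' Distance and dihedral time series for one replica, the standard visual
#' check that the trajectory hops between a short-distance / negative-
#' dihedral state and a long-distance / positive-dihedral state.
#'
#' @param features A feature tibble (see [make_two_state_trajectory()]).
#' @param replica Which replica to show.
#' @param distance_col,dihedral_col Column names.
#' @return A ggplot object (two facets sharing the time axis).
#' @export
plot_feature_series <- function(features, replica = 1,
                                distance_col = "s_cb",
                                dihedral_col = "dihedral") {
  f <- features[features$replica == replica, ]
  long <- tidyr::pivot_longer(
    f[, c("time", distance_col, dihedral_col)],
    cols = -"time", names_to = "descriptor")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~descriptor, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (ps)", y = NULL) +
    ggplot2::theme_minimal()
}
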