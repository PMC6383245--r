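#' Turn a grid into a plotting-ready tibble
#'
#' One row per unmasked cell with cell-center coordinates — the long format
#' `ggplot2::geom_raster()` expects.
#'
#' @param grid An [nb_grid()].
#' @return A tibble with columns `longitude`, `latitude`, `value`.
#' @export
grid_tibble <- function(grid) {
  stopifnot(inherits(grid, "nb_grid"))
  v <- grid$values
  idx <- which(!is.na(v), arr.ind = TRUE)
  xy <- cell_center(grid, idx[, 1], idx[, 2])
  tibble(longitude = xy$longitude, latitude = xy$latitude, value = v[idx])
}

#' Plot methods for grids, surfaces and classifications
#'
#' `autoplot()` renders a grid (or the grid inside a distance surface /
#' suitability map) as a `ggplot2::geom_raster()` map; categorical layers get
#' a discrete fill.
#'
#' @param object A `nb_grid`, `nb_distance_surface` or `nb_suitability`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name nichebox-autoplot
NULL

#' @rdname nichebox-autoplot
#' @method autoplot nb_grid
#' @export
autoplot.nb_grid <- function(object, ...) {
  df <- grid_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$longitude, .data$latitude)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "longitude", y = "latitude")
  if (object$kind == "categorical") {
    p + ggplot2::geom_raster(ggplot2::aes(fill = factor(.data$value))) +
      ggplot2::labs(fill = "class")
  } else {
    p + ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(fill = "value")
  }
}

#' @rdname nichebox-autoplot
#' @method autoplot nb_distance_surface
#' @export
autoplot.nb_distance_surface <- function(object, ...) {
  autoplot.nb_grid(object$grid) +
    ggplot2::labs(fill = "envelope distance",
                  title = "Distance to niche envelope (0 = maximum similarity)")
}

#' @rdname nichebox-autoplot
#' @method autoplot nb_suitability
#' @export
autoplot.nb_suitability <- function(object, ...) {
  autoplot.nb_grid(object$grid) +
    ggplot2::labs(fill = "suitability class",
                  title = "Suitability classes (class 0 = maximum similarity)")
}

#' Per-factor sample distribution plot
#'
#' Violin-style view of the raw occurrence sample values per factor, each
#' factor on its own free scale.
#'
#' @param samples Raw-space `nb_samples` tibble.
#' @return A ggplot object.
#' @export
plot_factor_distributions <- function(samples) {
  long <- tidyr::pivot_longer(as_tibble(as.data.frame(samples)),
                              dplyr::everything(),
                              names_to = "factor", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = "", y = .data$value)) +
    ggplot2::geom_violin(fill = "grey80") +
    ggplot2::geom_jitter(width = 0.05, alpha = 0.4, size = 0.6) +
    ggplot2::facet_wrap(~factor, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "value")
}
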