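#' Factor range table
#'
#' Per-factor summary of the raw-space occurrence samples: minimum, maximum, a
#' rendered "min–max" range string, arithmetic mean and sample standard
#' deviation (n − 1 denominator; `NA` for a single sample). These are the key
#' threshold values practitioners quote for a species' climatic niche.
#'
#' @param samples Raw-space `nb_samples` tibble (one column per factor).
#' @param units Optional named character vector of per-factor units.
#' @param digits Digits used when rendering the `range` string.
#' @return A tibble with columns `factor`, `unit`, `min`, `max`, `range`,
#'   `mean`, `sd`.
#' @export
range_table <- function(samples, units = NULL, digits = 6) {
  df <- as.data.frame(samples)
  if (nrow(df) == 0) nb_abort("cannot summarise zero samples.", "empty")
  if (!identical(sample_space(samples), "raw")) {
    nb_abort("range tables are computed on raw-space samples.", "space")
  }
  rows <- purrr::imap(as.list(df), function(v, nm) {
    tibble(
      factor = nm,
      unit = if (!is.null(units) && nm %in% names(units)) units[[nm]] else NA_character_,
      min = min(v), max = max(v),
      range = paste0(format(min(v), digits = digits), "–",
                     format(max(v), digits = digits)),
      mean = mean(v),
      sd = if (length(v) > 1) sd(v) else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

is_geographic <- function(crs) {
  !is.null(crs) && grepl("4326|WGS ?84|longlat|degree", crs, ignore.case = TRUE)
}

# per-row cell areas (km^2) for a grid; geographic grids use exact spherical
# bands on a sphere of radius 6,371,000 m, projected grids cellsize^2
cell_areas_km2 <- function(grid, earth_radius_m = 6371000) {
  nr <- nrow(grid$values)
  if (is.null(grid$crs)) {
    nb_abort("grid has no CRS; cannot compute areas. Set `crs` on the grid.",
             "georeference")
  }
  if (is_geographic(grid$crs)) {
    ymax <- grid_ymax(grid)
    lat_top <- ymax - (seq_len(nr) - 1) * grid$cellsize
    lat_bot <- lat_top - grid$cellsize
    dlon <- grid$cellsize * pi / 180
    (earth_radius_m / 1000)^2 * dlon *
      (sin(pmin(lat_top, 90) * pi / 180) - sin(pmax(lat_bot, -90) * pi / 180))
  } else {
    rep((grid$cellsize / 1000)^2, nr)
  }
}

#' Suitable-area summary per class
#'
#' Counts cells and accumulates area per suitability class. Projected grids
#' use cell count × pixel area; geographic (degree) grids use the exact
#' spherical band area per raster row on a sphere of radius 6,371,000 m, so
#' cell area shrinks with cos(latitude).
#'
#' @param map An [classify_distance()] result, or a binary `nb_mask` (classes
#'   0/1), or any categorical [nb_grid()].
#' @param labels Optional named character vector mapping class ids to labels.
#' @param earth_radius_m Sphere radius for geographic grids (m).
#' @return A tibble with columns `class`, `label`, `n_cells`, `area_km2`.
#'   Class areas partition the total unmasked area.
#' @export
area_summary <- function(map, labels = NULL, earth_radius_m = 6371000) {
  grid <- if (inherits(map, "nb_suitability")) map$grid else map
  stopifnot(inherits(grid, "nb_grid"))
  row_area <- cell_areas_km2(grid, earth_radius_m)
  v <- grid$values
  cls <- sort(unique(v[!is.na(v)]))
  if (length(cls) == 0) {
    return(tibble(class = integer(0), label = character(0),
                  n_cells = integer(0), area_km2 = numeric(0)))
  }
  area_m <- matrix(row_area, nrow(v), ncol(v))
  rows <- purrr::map(cls, function(k) {
    sel <- !is.na(v) & v == k
    tibble(class = as.integer(k),
           label = if (!is.null(labels) && as.character(k) %in% names(labels))
             labels[[as.character(k)]]
           else if (k == 0 && inherits(map, "nb_suitability"))
             "maximum ecological similarity"
           else NA_character_,
           n_cells = sum(sel),
           area_km2 = sum(area_m[sel]))
  })
  dplyr::bind_rows(rows)
}
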