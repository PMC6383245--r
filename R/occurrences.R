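#' Read presence-only occurrence records
#'
#' Reads a CSV with (at least) the columns `species`, `longitude`, `latitude`
#' in WGS84 decimal degrees. Duplicate coordinates are kept — deduplication
#' happens later at the raster-cell level in [extract_values()]. Rows with
#' coordinates outside valid bounds raise an error naming the offending row.
#'
#' @param path Path to the occurrence CSV.
#' @return A tibble of class `nb_occurrences` with columns `species`,
#'   `longitude`, `latitude`.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) {
    nb_abort(sprintf("occurrence file not found: '%s'", path), "read")
  }
  occ <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("species", "longitude", "latitude")
  if (!all(need %in% names(occ))) {
    nb_abort("occurrence CSV must have columns species, longitude, latitude.",
             "format")
  }
  as_occurrences(occ[need])
}

#' Coerce a data frame to an occurrence set
#'
#' Validates coordinate bounds (longitude in \[-180, 180\], latitude in
#' \[-90, 90\]) and tags the tibble.
#'
#' @param df Data frame with `species`, `longitude`, `latitude` columns.
#' @return A tibble of class `nb_occurrences`.
#' @export
as_occurrences <- function(df) {
  df <- as_tibble(df)
  bad <- which(!is.finite(df$longitude) | !is.finite(df$latitude) |
               df$longitude < -180 | df$longitude > 180 |
               df$latitude < -90 | df$latitude > 90)
  if (length(bad)) {
    nb_abort(sprintf(
      "invalid coordinates in occurrence row(s) %s (longitude must be in [-180, 180], latitude in [-90, 90]).",
      paste(head(bad, 5), collapse = ", ")), "coords")
  }
  class(df) <- c("nb_occurrences", class(df))
  df
}

#' Rasterize occurrences to unique cells
#'
#' Maps each occurrence point to its (row, col) cell on `grid`, drops points
#' outside the extent, and optionally collapses multiple points per cell to
#' one (first occurrence kept, input order preserved).
#'
#' @param grid Reference [nb_grid()] (or an [nb_stack()], whose first layer is
#'   used).
#' @param occ An `nb_occurrences` tibble.
#' @param dedup Collapse points sharing a cell? Default `TRUE`.
#' @return Tibble with columns `row`, `col`; attribute `n_out_of_extent`.
#' @export
occurrence_cells <- function(grid, occ, dedup = TRUE) {
  if (inherits(grid, "nb_stack")) grid <- grid$layers[[1]]
  cells <- cell_of(grid, occ$longitude, occ$latitude)
  out <- is.na(cells$row)
  cells <- cells[!out, , drop = FALSE]
  if (dedup) {
    cells <- dplyr::distinct(cells, .data$row, .data$col)
  }
  attr(cells, "n_out_of_extent") <- sum(out)
  cells
}

#' Extract per-occurrence environmental values
#'
#' Builds the sample matrix: one row of layer values per retained occurrence
#' cell, in input order. Points that fall outside the grid extent or on a
#' nodata cell in **any** layer are dropped with a warning that reports the
#' counts; with `dedup = TRUE` (default) multiple points in one cell
#' contribute a single row, since the envelope model operates on raster cells.
#'
#' @param stack An aligned [nb_stack()].
#' @param occ An `nb_occurrences` tibble (see [read_occurrences()]).
#' @param dedup Collapse points sharing a raster cell? Default `TRUE`.
#' @return A tibble of class `nb_samples` (one column per layer) with
#'   attributes `space` (the stack's value space), `cells` (tibble of
#'   `row`/`col`), and `dropped` (named counts: `out_of_extent`, `nodata`).
#' @export
extract_values <- function(stack, occ, dedup = TRUE) {
  stopifnot(inherits(stack, "nb_stack"))
  assert_aligned(stack)
  if (nrow(occ) == 0) nb_abort("occurrence set is empty.", "empty")
  ref <- stack$layers[[1]]
  cells <- occurrence_cells(ref, occ, dedup = dedup)
  n_out <- attr(cells, "n_out_of_extent")
  vals <- purrr::map(stack$layers, function(g) {
    g$values[cbind(cells$row, cells$col)]
  })
  m <- as_tibble(vals)
  keep <- !purrr::reduce(purrr::map(vals, is.na), `|`,
                         .init = rep(FALSE, nrow(cells)))
  n_nodata <- sum(!keep)
  m <- m[keep, , drop = FALSE]
  cells <- cells[keep, , drop = FALSE]
  if (nrow(m) == 0) {
    nb_abort("no usable occurrence cells: all points fell outside the extent or on nodata.",
             "empty_sample")
  }
  if (n_out + n_nodata > 0) {
    nb_warn(sprintf("dropped %d occurrence point(s): %d outside extent, %d on nodata cells.",
                    n_out + n_nodata, n_out, n_nodata), "dropped_points")
  }
  new_samples(m, space = stack$space, cells = cells,
              dropped = c(out_of_extent = n_out, nodata = n_nodata))
}

new_samples <- function(df, space, cells = NULL, dropped = NULL) {
  df <- as_tibble(df)
  attr(df, "space") <- space
  attr(df, "cells") <- cells
  attr(df, "dropped") <- dropped
  class(df) <- unique(c("nb_samples", class(df)))
  df
}

sample_space <- function(x, default = "raw") {
  attr(x, "space") %||% default
}
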