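# small in-code fixtures shared across test files

tiny_grid <- function(values = matrix(as.numeric(1:6), 2, 3), cellsize = 1,
                      crs = "EPSG:4326", kind = "continuous") {
  nb_grid(values, xll = 0, yll = 0, cellsize = cellsize, crs = crs, kind = kind)
}

# stack of constant-free layers with known values on a shared 1-degree grid
tiny_stack <- function(n_layers = 2, nr = 4, nc = 5, seed = 11) {
  layers <- withr::with_seed(seed, {
    lapply(seq_len(n_layers), function(j) {
      tiny_grid(matrix(stats::rnorm(nr * nc, mean = 10 * j, sd = 2), nr, nc))
    })
  })
  nb_stack(layers, names = paste0("L", seq_len(n_layers)))
}

# occurrences at the centers of the given (row, col) cells of a grid
occ_at_cells <- function(grid, rows, cols, species = "test") {
  xy <- cell_center(grid, rows, cols)
  as_occurrences(tibble::tibble(species = species,
                                longitude = xy$longitude,
                                latitude = xy$latitude))
}

write_asc_fixture <- function(lines, path = tempfile(fileext = ".asc")) {
  writeLines(lines, path)
  path
}

asc_2x2 <- function(nodata = NULL) {
  hdr <- c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0", "cellsize 1")
  if (!is.null(nodata)) hdr <- c(hdr, paste("NODATA_value", nodata))
  write_asc_fixture(c(hdr, "1 2", "3 4"))
}

# independent closed-form oracle: Euclidean distance from a point to a box
clamp_box_distance <- function(p, lo, hi) {
  sqrt(sum(pmax(0, pmax(lo - p, p - hi))^2))
}

# independent re-derivation of per-row band areas for the conservation check
cell_areas_km2_ref <- function(g, R = 6371) {
  nr <- nrow(g$values)
  ymax <- g$yll + nr * g$cellsize
  top <- ymax - (seq_len(nr) - 1) * g$cellsize
  R^2 * (g$cellsize * pi / 180) *
    (sin(top * pi / 180) - sin((top - g$cellsize) * pi / 180))
}
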