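#' Georeferenced raster grid
#'
#' `nb_grid()` wraps a numeric matrix as a single-band raster layer with a
#' simple affine georeference (lower-left corner, square cells) and an optional
#' coordinate reference system label. Missing cells are encoded as `NA`
#' (the nodata mask). Row 1 of the matrix is the **top** (northernmost) row,
#' matching the on-disk order of ESRI ASCII grids.
#'
#' @param values Numeric matrix of cell values; `NA` marks nodata cells.
#' @param xll,yll Coordinates of the lower-left corner of the grid.
#' @param cellsize Cell edge length (same units as `xll`/`yll`); must be > 0.
#' @param crs Optional CRS label (e.g. `"EPSG:4326"`); `NULL` if unknown.
#' @param kind `"continuous"` or `"categorical"`. Categorical grids must hold
#'   integer codes in all non-nodata cells.
#' @return An object of class `nb_grid`.
#' @examples
#' g <- nb_grid(matrix(1:6, 2, 3), xll = 0, yll = 0, cellsize = 1)
#' dim(g)
#' @export
nb_grid <- function(values, xll = 0, yll = 0, cellsize = 1,
                    crs = NULL, kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    nb_abort("`values` must be a numeric matrix.", "grid")
  }
  if (!is.numeric(cellsize) || length(cellsize) != 1 || !is.finite(cellsize) ||
      cellsize <= 0) {
    nb_abort("`cellsize` must be a single positive number.", "grid")
  }
  v <- values[!is.na(values)]
  if (kind == "categorical" && length(v) && any(v != round(v))) {
    nb_abort("categorical grid contains non-integer codes.", "grid")
  }
  structure(
    list(values = values, xll = as.numeric(xll), yll = as.numeric(yll),
         cellsize = as.numeric(cellsize), crs = crs, kind = kind),
    class = "nb_grid"
  )
}

#' @export
dim.nb_grid <- function(x) dim(x$values)

#' @export
print.nb_grid <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<nb_grid> %d x %d cells (%s), cellsize %g, origin (%g, %g), crs %s\n",
              d[1], d[2], x$kind, x$cellsize, x$xll, x$yll,
              x$crs %||% "<none>"))
  cat(sprintf("  %d nodata cells; value range [%s, %s]\n",
              sum(is.na(x$values)),
              format(suppressWarnings(min(x$values, na.rm = TRUE))),
              format(suppressWarnings(max(x$values, na.rm = TRUE)))))
  invisible(x)
}

grid_ymax <- function(g) g$yll + nrow(g$values) * g$cellsize
grid_xmax <- function(g) g$xll + ncol(g$values) * g$cellsize

same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol &&
    identical(a$crs %||% "", b$crs %||% "")
}

#' Locate points on a grid
#'
#' Converts longitude/latitude (or projected x/y) coordinates to 1-based
#' (row, col) cell indices. The convention is half-open: a point exactly on a
#' cell edge belongs to the cell whose fractional index floors to it, with row
#' 1 at the top edge of the raster. Points outside the extent get `NA` indices.
#'
#' @param grid An [nb_grid()].
#' @param lon,lat Coordinate vectors of equal length.
#' @return A tibble with columns `row`, `col` (`NA` when out of extent).
#' @export
cell_of <- function(grid, lon, lat) {
  fr <- (grid_ymax(grid) - lat) / grid$cellsize
  fc <- (lon - grid$xll) / grid$cellsize
  row <- floor(fr) + 1L
  col <- floor(fc) + 1L
  bad <- row < 1L | row > nrow(grid$values) | col < 1L | col > ncol(grid$values)
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  tibble(row = as.integer(row), col = as.integer(col))
}

#' Cell-center coordinates
#'
#' Inverse of [cell_of()]: returns the coordinates of the center of each
#' (row, col) cell.
#'
#' @inheritParams cell_of
#' @param row,col Integer cell indices (1-based, row 1 at the top).
#' @return A tibble with columns `longitude`, `latitude`.
#' @export
cell_center <- function(grid, row, col) {
  tibble(
    longitude = grid$xll + (col - 0.5) * grid$cellsize,
    latitude  = grid_ymax(grid) - (row - 0.5) * grid$cellsize
  )
}

#' Raster layer stack
#'
#' An ordered, named collection of [nb_grid()] layers intended to share one
#' geometry. Construction requires unique names; geometric agreement is
#' checked by [check_aligned()] (and asserted by every operation that consumes
#' a stack), never silently repaired.
#'
#' @param layers A list of [nb_grid()] objects.
#' @param names Character vector of unique layer names (defaults to the list
#'   names).
#' @param space Value space of the layers: `"raw"`, `"standardized"` or
#'   `"pca"`.
#' @return An object of class `nb_stack`.
#' @export
nb_stack <- function(layers, names = NULL, space = "raw") {
  if (!is.list(layers) || length(layers) == 0) {
    nb_abort("`layers` must be a nonempty list of nb_grid objects.", "stack")
  }
  if (!all(vapply(layers, inherits, logical(1), "nb_grid"))) {
    nb_abort("all elements of `layers` must be nb_grid objects.", "stack")
  }
  names <- names %||% base::names(layers)
  if (is.null(names) || anyNA(names) || any(names == "")) {
    nb_abort("every layer needs a name.", "stack")
  }
  if (anyDuplicated(names)) {
    nb_abort("layer names must be unique.", "stack")
  }
  base::names(layers) <- names
  structure(list(layers = layers, space = space), class = "nb_stack")
}

#' @export
length.nb_stack <- function(x) length(x$layers)

#' @export
names.nb_stack <- function(x) names(x$layers)

#' @export
print.nb_stack <- function(x, ...) {
  g <- x$layers[[1]]
  cat(sprintf("<nb_stack> %d layers, %d x %d cells, space '%s'\n",
              length(x), nrow(g$values), ncol(g$values), x$space))
  cat(" ", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Check that all layers of a stack are co-registered
#'
#' Verifies that every layer shares the shape, affine georeference and CRS of
#' the first layer. No resampling is ever attempted: misalignment is reported,
#' and [assert_aligned()] turns it into a hard error naming the first
#' offending layer.
#'
#' @param stack An [nb_stack()].
#' @return A tibble with one row per layer: `layer`, `aligned`, `detail`.
#' @export
check_aligned <- function(stack) {
  stopifnot(inherits(stack, "nb_stack"))
  ref <- stack$layers[[1]]
  rows <- purrr::imap(stack$layers, function(g, nm) {
    ok <- same_geometry(ref, g)
    detail <- if (ok) "" else {
      if (!identical(dim(g$values), dim(ref$values))) "shape differs"
      else if (!identical(g$crs %||% "", ref$crs %||% "")) "crs differs"
      else "transform differs"
    }
    tibble(layer = nm, aligned = ok, detail = detail)
  })
  dplyr::bind_rows(rows)
}

#' @rdname check_aligned
#' @export
assert_aligned <- function(stack) {
  rep <- check_aligned(stack)
  bad <- dplyr::filter(rep, !.data$aligned)
  if (nrow(bad) > 0) {
    nb_abort(
      sprintf("stack is misaligned: layer '%s' (%s). Align inputs upstream; no resampling is performed.",
              bad$layer[1], bad$detail[1]),
      "misaligned"
    )
  }
  invisible(stack)
}

# ncell x nlayer matrix of cell values, column-major cell order
stack_matrix <- function(stack) {
  m <- vapply(stack$layers, function(g) as.vector(g$values),
              numeric(length(stack$layers[[1]]$values)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  colnames(m) <- names(stack)
  m
}

# rebuild a stack from a cell matrix using a template geometry
matrix_to_stack <- function(m, template, names, space) {
  g0 <- template$layers[[1]]
  layers <- lapply(seq_len(ncol(m)), function(j) {
    nb_grid(matrix(m[, j], nrow = nrow(g0$values)),
            xll = g0$xll, yll = g0$yll, cellsize = g0$cellsize,
            crs = g0$crs, kind = "continuous")
  })
  nb_stack(layers, names = names, space = space)
}
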