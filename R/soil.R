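#' Suitable soil classes at occurrence cells
#'
#' The set of distinct categorical soil codes observed at the occurrence
#' cells, ignoring nodata. Every occurrence cell with valid soil data is soil-
#' suitable under the derived set by construction.
#'
#' @param soil_grid A categorical [nb_grid()] of integer soil-unit codes.
#' @param occ_cells Tibble with `row`, `col` columns (see
#'   [occurrence_cells()] or the `cells` attribute of [extract_values()]).
#' @param labels Optional named character vector or two-column data frame
#'   (`code`, `name`) mapping codes to class names.
#' @return A tibble of class `nb_soil_classes` with columns `code` and
#'   `label` (`NA` where unknown).
#' @export
suitable_soil_classes <- function(soil_grid, occ_cells, labels = NULL) {
  stopifnot(inherits(soil_grid, "nb_grid"))
  if (soil_grid$kind != "categorical") {
    nb_abort("`soil_grid` must be a categorical grid.", "soil")
  }
  if (is.null(occ_cells) || nrow(occ_cells) == 0) {
    nb_abort("`occ_cells` is empty.", "empty")
  }
  codes <- soil_grid$values[cbind(occ_cells$row, occ_cells$col)]
  codes <- sort(unique(codes[!is.na(codes)]))
  if (length(codes) == 0) {
    nb_abort("all occurrence cells fall on soil nodata; no suitable class can be derived.",
             "empty_sample")
  }
  lab <- rep(NA_character_, length(codes))
  if (!is.null(labels)) {
    if (is.data.frame(labels)) {
      labels <- setNames(as.character(labels$name), labels$code)
    }
    lab <- unname(labels[as.character(codes)])
  }
  out <- tibble(code = as.integer(codes), label = lab)
  class(out) <- c("nb_soil_classes", class(out))
  out
}

#' Binary soil-suitability mask
#'
#' Cell value 1 where the soil code belongs to the suitable set, 0 elsewhere;
#' nodata propagates.
#'
#' @inheritParams suitable_soil_classes
#' @param classes An `nb_soil_classes` tibble, or a plain vector of codes.
#' @return A binary [nb_grid()] (class `nb_mask`): 1 = suitable.
#' @export
soil_mask <- function(soil_grid, classes) {
  stopifnot(inherits(soil_grid, "nb_grid"))
  codes <- if (is.data.frame(classes)) classes$code else classes
  if (length(codes) == 0) nb_abort("`classes` is empty.", "soil")
  v <- soil_grid$values
  m <- matrix(as.numeric(v %in% codes), nrow(v), ncol(v))
  m[is.na(v)] <- NA
  new_mask(m, soil_grid)
}

new_mask <- function(m, template) {
  g <- nb_grid(m, xll = template$xll, yll = template$yll,
               cellsize = template$cellsize, crs = template$crs,
               kind = "categorical")
  class(g) <- c("nb_mask", class(g))
  g
}

#' Binary climate-suitability mask from a classified surface
#'
#' Cell value 1 where the suitability class belongs to `suitable_classes`
#' (default: class 0 only, the maximum-ecological-similarity region).
#'
#' @param map An [classify_distance()] result.
#' @param suitable_classes Integer class ids to treat as suitable.
#' @return A binary [nb_grid()] (class `nb_mask`).
#' @export
climate_mask <- function(map, suitable_classes = 0L) {
  stopifnot(inherits(map, "nb_suitability"))
  if (length(suitable_classes) == 0) {
    nb_abort("`suitable_classes` is empty.", "classify")
  }
  known <- 0:(map$n_classes - 1L)
  unknown <- setdiff(suitable_classes, known)
  if (length(unknown)) {
    nb_abort(sprintf("unknown class id(s): %s (map has classes %d..%d).",
                     paste(unknown, collapse = ", "), 0L, map$n_classes - 1L),
             "classify")
  }
  v <- map$grid$values
  m <- matrix(as.numeric(v %in% suitable_classes), nrow(v), ncol(v))
  m[is.na(v)] <- NA
  new_mask(m, map$grid)
}

#' Intersect two binary masks (overlay rule)
#'
#' Adds the two 0/1 layers and extracts the cells summing to 2 — i.e. cells
#' suitable in both inputs. Commutative, associative and idempotent. Nodata in
#' either input yields nodata (unknown is not treated as unsuitable).
#'
#' @param a,b Aligned binary masks ([nb_grid()] with 0/1 values).
#' @return A binary [nb_grid()] (class `nb_mask`).
#' @export
intersect_masks <- function(a, b) {
  stopifnot(inherits(a, "nb_grid"), inherits(b, "nb_grid"))
  if (!same_geometry(a, b)) {
    nb_abort("masks are misaligned; no resampling is performed.", "misaligned")
  }
  ok <- c(a$values[!is.na(a$values)], b$values[!is.na(b$values)])
  if (length(ok) && !all(ok %in% c(0, 1))) {
    nb_abort("masks must contain only 0/1 values outside nodata.", "soil")
  }
  s <- a$values + b$values
  m <- matrix(as.numeric(s == 2), nrow(s), ncol(s))
  m[is.na(s)] <- NA
  new_mask(m, a)
}

#' Numeric soil-attribute range filter
#'
#' Optional refinement using topsoil attribute layers (gravel, sand, silt,
#' clay fractions, pH, organic carbon, ...): a cell passes (value 1) only if
#' every attribute lies within the occurrence-derived `[min, max]` range for
#' that attribute — a per-attribute one-dimensional envelope zero-distance
#' test. Off by default in the pipeline; the categorical class mask is the
#' primary soil criterion.
#'
#' @param attr_stack An aligned [nb_stack()] of numeric soil-attribute layers.
#' @param occ_cells Tibble with `row`, `col` columns.
#' @return A binary [nb_grid()] (class `nb_mask`).
#' @export
attribute_filter <- function(attr_stack, occ_cells) {
  stopifnot(inherits(attr_stack, "nb_stack"))
  assert_aligned(attr_stack)
  if (length(attr_stack) == 0) nb_abort("attribute stack is empty.", "empty")
  if (is.null(occ_cells) || nrow(occ_cells) == 0) {
    nb_abort("`occ_cells` is empty.", "empty")
  }
  idx <- cbind(occ_cells$row, occ_cells$col)
  samp <- purrr::map(attr_stack$layers, function(g) g$values[idx])
  keep <- !purrr::reduce(purrr::map(samp, is.na), `|`)
  if (!any(keep)) {
    nb_abort("all occurrence cells lack attribute data.", "empty_sample")
  }
  env <- envelope_fit(as_tibble(purrr::map(samp, ~ .x[keep])))
  m <- stack_matrix(attr_stack)
  bad <- rowSums(is.na(m)) > 0
  inside <- rep(NA_real_, nrow(m))
  if (any(!bad)) {
    d <- envelope_distance(m[!bad, , drop = FALSE], env)
    inside[!bad] <- as.numeric(d == 0)
  }
  g0 <- attr_stack$layers[[1]]
  new_mask(matrix(inside, nrow = nrow(g0$values)), g0)
}
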