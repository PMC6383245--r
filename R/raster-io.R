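#' Read a raster layer from an ESRI ASCII grid
#'
#' Reads a single-band raster in ESRI ASCII grid format (`.asc`): a six-line
#' header (`ncols`, `nrows`, `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`,
#' `cellsize`, optional `NODATA_value`) followed by the cell values, top row
#' first. Cells equal to the declared nodata value are masked (`NA`). If a
#' `.prj` sidecar file sits next to the raster its first line is taken as the
#' CRS label.
#'
#' @param path Path to the `.asc` file.
#' @param kind Layer kind, `"continuous"` (default) or `"categorical"`.
#' @return An [nb_grid()].
#' @export
read_raster <- function(path, kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    nb_abort(sprintf("raster file not found: '%s'", path), "read")
  }
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) nb_abort(
                      sprintf("cannot read '%s': %s", path, conditionMessage(e)),
                      "read"))
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+\\S+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- parts[2]
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)) ||
      !any(c("xllcorner", "xllcenter") %in% names(hdr)) ||
      !any(c("yllcorner", "yllcenter") %in% names(hdr))) {
    nb_abort(sprintf("'%s' is not an ESRI ASCII grid (bad or missing header).", path),
             "format")
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- as.numeric(hdr$cellsize)
  if (anyNA(c(nc, nr, cs)) || nc < 1 || nr < 1 || !is.finite(cs) || cs <= 0) {
    nb_abort(sprintf("'%s': invalid raster dimensions or cellsize.", path), "format")
  }
  xll <- if (!is.null(hdr$xllcorner)) as.numeric(hdr$xllcorner) else
    as.numeric(hdr$xllcenter) - cs / 2
  yll <- if (!is.null(hdr$yllcorner)) as.numeric(hdr$yllcorner) else
    as.numeric(hdr$yllcenter) - cs / 2
  body <- paste(lines[i:length(lines)], collapse = " ")
  vals <- suppressWarnings(as.numeric(strsplit(trimws(body), "\\s+")[[1]]))
  if (length(vals) != nr * nc || anyNA(vals)) {
    nb_abort(sprintf("'%s': raster body is malformed (expected %d numeric values).",
                     path, nr * nc), "format")
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) {
    m[m == as.numeric(hdr$nodata_value)] <- NA
  }
  prj <- sub("\\.asc$", ".prj", path, ignore.case = TRUE)
  crs <- if (!identical(prj, path) && file.exists(prj)) {
    trimws(readLines(prj, warn = FALSE, n = 1))
  } else NULL
  nb_grid(m, xll = xll, yll = yll, cellsize = cs, crs = crs, kind = kind)
}

#' Write a raster layer as an ESRI ASCII grid
#'
#' The written file round-trips through [read_raster()] to an identical grid:
#' values, nodata mask, georeference and (via a `.prj` sidecar) CRS.
#' Categorical grids are written as plain integers; continuous grids with
#' full double precision.
#'
#' @param grid An [nb_grid()].
#' @param path Output path (conventionally `.asc`).
#' @param nodata Numeric value used to encode masked cells on disk. Must not
#'   collide with a data value.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "nb_grid"))
  v <- grid$values
  if (any(v == nodata, na.rm = TRUE)) {
    nb_abort("nodata sentinel collides with a data value; pick another.", "write")
  }
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.17g", grid$xll),
    sprintf("yllcorner %.17g", grid$yll),
    sprintf("cellsize %.17g", grid$cellsize),
    sprintf("NODATA_value %.17g", nodata)
  )
  fmt <- if (grid$kind == "categorical") "%d" else "%.17g"
  enc <- function(x) {
    out <- if (grid$kind == "categorical") sprintf(fmt, as.integer(x))
           else sprintf(fmt, x)
    out[is.na(x)] <- sprintf("%.17g", nodata)
    out
  }
  rows <- apply(v, 1, function(r) paste(enc(r), collapse = " "))
  ok <- tryCatch({
    writeLines(c(hdr, rows), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) nb_abort(sprintf("cannot write '%s'.", path), "write")
  if (!is.null(grid$crs)) {
    writeLines(grid$crs, sub("\\.asc$", ".prj", path, ignore.case = TRUE))
  }
  invisible(path)
}

#' Read a layer manifest into a stack
#'
#' The manifest is a CSV with columns `name`, `path` and optionally `kind`
#' (`continuous`/`categorical`); relative paths are resolved against the
#' manifest's directory. Layer order follows the manifest.
#'
#' @param path Manifest CSV path.
#' @return An [nb_stack()] in raw space.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) {
    nb_abort(sprintf("manifest not found: '%s'", path), "read")
  }
  man <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("name", "path") %in% names(man))) {
    nb_abort("manifest must have columns 'name' and 'path'.", "format")
  }
  if (!"kind" %in% names(man)) man$kind <- "continuous"
  base <- dirname(path)
  layers <- purrr::pmap(man[c("name", "path", "kind")], function(name, path, kind) {
    p <- if (grepl("^(/|[A-Za-z]:)", path)) path else file.path(base, path)
    read_raster(p, kind = kind)
  })
  nb_stack(layers, names = man$name, space = "raw")
}
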