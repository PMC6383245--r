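#' Envelope-distance surface over a raster stack
#'
#' Computes the Euclidean envelope distance at every cell of an aligned stack
#' (which must be in the same value space the envelope was fitted in). Nodata
#' in any layer makes the output cell nodata. The observed distance range
#' `[min_d, max_d]` over unmasked cells is recorded for classification.
#'
#' @param stack An [nb_stack()] whose layers match the envelope dimensions
#'   (by name and order).
#' @param env An [envelope_fit()] result.
#' @param aggregate `"euclidean"` (default) or `"sumsq"`; see
#'   [envelope_distance()].
#' @return An object of class `nb_distance_surface`: fields `grid`
#'   ([nb_grid()] of distances), `min_d`, `max_d`, `aggregate`.
#' @export
distance_surface <- function(stack, env, aggregate = c("euclidean", "sumsq")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(stack, "nb_stack"), inherits(env, "nb_envelope"))
  assert_aligned(stack)
  if (!identical(stack$space, attr(env, "space"))) {
    nb_abort(sprintf("value-space mismatch: envelope is '%s', stack is '%s'.",
                     attr(env, "space"), stack$space), "space")
  }
  if (!identical(names(stack), env$dimension)) {
    nb_abort("stack layer names/order do not match the envelope dimensions.",
             "mismatch")
  }
  m <- stack_matrix(stack)
  bad <- rowSums(is.na(m)) > 0
  d <- rep(NA_real_, nrow(m))
  if (any(!bad)) {
    mm <- m[!bad, , drop = FALSE]
    attr(mm, "space") <- stack$space
    d[!bad] <- envelope_distance(mm, env, aggregate = aggregate)
  }
  g0 <- stack$layers[[1]]
  grid <- nb_grid(matrix(d, nrow = nrow(g0$values)),
                  xll = g0$xll, yll = g0$yll, cellsize = g0$cellsize,
                  crs = g0$crs, kind = "continuous")
  structure(
    list(grid = grid,
         min_d = if (any(!bad)) min(d, na.rm = TRUE) else NA_real_,
         max_d = if (any(!bad)) max(d, na.rm = TRUE) else NA_real_,
         aggregate = aggregate),
    class = "nb_distance_surface"
  )
}

#' @export
print.nb_distance_surface <- function(x, ...) {
  cat(sprintf("<nb_distance_surface> distances in [%g, %g] (%s aggregation)\n",
              x$min_d, x$max_d, x$aggregate))
  print(x$grid)
  invisible(x)
}

#' Classify a distance surface into suitability classes
#'
#' Class 0 is reserved for cells at distance exactly 0 — the region of maximum
#' ecological similarity, where every factor lies within the occurrence-derived
#' range. Positive distances are split into `n_classes - 1` equal-width
#' intervals over `(0, max_d]`, half-open on the left (ties at a break go to
#' the lower class). Explicit `breaks` (strictly increasing, interior
#' thresholds) override the equal-width scheme. Nodata propagates.
#'
#' @param surface An [distance_surface()] result.
#' @param n_classes Total number of classes including class 0; >= 2 unless
#'   `breaks` is given.
#' @param breaks Optional strictly increasing positive thresholds `b1 < ... <
#'   bk`: class `i` covers `(b[i-1], b[i]]` with `b0 = 0`; distances above
#'   `bk` are assigned the top class `k`.
#' @return An object of class `nb_suitability`: fields `grid` (categorical
#'   [nb_grid()] of class ids), `breaks`, `n_classes`.
#' @export
classify_distance <- function(surface, n_classes = 5, breaks = NULL) {
  stopifnot(inherits(surface, "nb_distance_surface"))
  d <- surface$grid$values
  if (is.null(breaks)) {
    if (!is.numeric(n_classes) || n_classes < 2) {
      nb_abort("`n_classes` must be >= 2 (class 0 plus at least one positive bin).",
               "classify")
    }
    maxd <- surface$max_d
    breaks <- if (!is.na(maxd) && maxd > 0) {
      seq(0, maxd, length.out = n_classes)[-1]
    } else {
      numeric(0)  # all distances are 0: everything is class 0
    }
  } else {
    if (is.unsorted(breaks, strictly = TRUE) || any(breaks <= 0)) {
      nb_abort("`breaks` must be strictly increasing and positive.", "classify")
    }
  }
  cls <- matrix(NA_real_, nrow(d), ncol(d))
  ok <- !is.na(d)
  cls[ok & d == 0] <- 0
  pos <- ok & d > 0
  if (any(pos)) {
    if (length(breaks) == 0) {
      nb_abort("surface has positive distances but no positive bins.", "classify")
    }
    # (b[i-1], b[i]] bins: count strictly-smaller breaks, ties to lower class
    idx <- findInterval(d[pos], breaks, left.open = TRUE) + 1L
    idx[idx > length(breaks)] <- length(breaks)
    cls[pos] <- idx
  }
  g <- surface$grid
  grid <- nb_grid(cls, xll = g$xll, yll = g$yll, cellsize = g$cellsize,
                  crs = g$crs, kind = "categorical")
  structure(
    list(grid = grid, breaks = breaks, n_classes = length(breaks) + 1L),
    class = "nb_suitability"
  )
}

#' @export
print.nb_suitability <- function(x, ...) {
  cat(sprintf("<nb_suitability> %d classes (0 = maximum ecological similarity)\n",
              x$n_classes))
  tab <- table(x$grid$values)
  cat("  cells per class:", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}
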