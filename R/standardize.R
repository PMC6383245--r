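#' Fit per-layer linear standardization
#'
#' Records, per layer (column), the minimum and maximum of the fitted data.
#' [standardize_apply()] then maps values linearly so the fitted minimum goes
#' to `new_min` (0) and the fitted maximum to `new_max` (100); values outside
#' the fitted range extrapolate linearly. Layers whose minimum equals their
#' maximum are flagged `degenerate` and are excluded (with a warning) when the
#' standardization is applied, since their scale is undefined.
#'
#' @param x An `nb_samples` tibble / data frame (per-column fit), a numeric
#'   vector, or an [nb_stack()] (per-layer fit over unmasked cells).
#' @param new_min,new_max Target bounds; defaults 0 and 100.
#' @return A tibble of class `nb_standardization` with columns `layer`,
#'   `min`, `max`, `degenerate`, and attributes `new_min`, `new_max`.
#' @export
standardize_fit <- function(x, new_min = 0, new_max = 100) {
  cols <- standardize_columns(x)
  rows <- purrr::imap(cols, function(v, nm) {
    v <- v[is.finite(v)]
    if (length(v) == 0) {
      nb_abort(sprintf("layer '%s' has no finite values to standardize.", nm),
               "empty")
    }
    tibble(layer = nm, min = min(v), max = max(v), degenerate = min(v) == max(v))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "new_min") <- new_min
  attr(out, "new_max") <- new_max
  class(out) <- c("nb_standardization", class(out))
  out
}

standardize_columns <- function(x) {
  if (inherits(x, "nb_stack")) {
    purrr::map(x$layers, function(g) as.vector(g$values))
  } else if (is.data.frame(x)) {
    as.list(x)
  } else if (is.numeric(x)) {
    list(value = x)
  } else {
    nb_abort("cannot standardize this object.", "type")
  }
}

#' Apply (or invert) a fitted standardization
#'
#' Maps `v' = (v - min) / (max - min) * (new_max - new_min) + new_min`
#' column-by-column. The transform is affine and order-preserving; the fitted
#' extremes map exactly to `new_min` and `new_max` and out-of-range values
#' extrapolate linearly (prediction rasters routinely exceed the
#' occurrence-derived extremes). Degenerate layers are dropped with a warning.
#'
#' @param x Samples tibble, numeric vector, or [nb_stack()] matching the
#'   layers of `params`.
#' @param params An `nb_standardization` from [standardize_fit()].
#' @return Object of the same shape as `x` (minus degenerate layers), in
#'   `"standardized"` space. For a stack the result is an [nb_stack()] whose
#'   space tag is `"standardized"`.
#' @export
standardize_apply <- function(x, params) {
  stopifnot(inherits(params, "nb_standardization"))
  p <- drop_degenerate(params)
  lo <- attr(params, "new_min"); hi <- attr(params, "new_max")
  f <- function(v, mn, mx) (v - mn) / (mx - mn) * (hi - lo) + lo
  transform_like(x, p, f)
}

#' @rdname standardize_apply
#' @export
standardize_invert <- function(x, params) {
  stopifnot(inherits(params, "nb_standardization"))
  p <- drop_degenerate(params)
  lo <- attr(params, "new_min"); hi <- attr(params, "new_max")
  f <- function(v, mn, mx) (v - lo) / (hi - lo) * (mx - mn) + mn
  out <- transform_like(x, p, f)
  if (is.data.frame(out)) attr(out, "space") <- "raw"
  if (inherits(out, "nb_stack")) out$space <- "raw"
  out
}

drop_degenerate <- function(params) {
  if (any(params$degenerate)) {
    nb_warn(sprintf(
      "excluding degenerate (constant) layer(s) from standardization: %s",
      paste(params$layer[params$degenerate], collapse = ", ")),
      "degenerate_layer")
  }
  params[!params$degenerate, , drop = FALSE]
}

transform_like <- function(x, p, f) {
  if (inherits(x, "nb_stack")) {
    miss <- setdiff(p$layer, names(x))
    if (length(miss)) {
      nb_abort(sprintf("stack lacks layer(s): %s", paste(miss, collapse = ", ")),
               "mismatch")
    }
    layers <- purrr::pmap(p, function(layer, min, max, ...) {
      g <- x$layers[[layer]]
      g$values <- f(g$values, min, max)
      g
    })
    nb_stack(layers, names = p$layer, space = "standardized")
  } else if (is.data.frame(x)) {
    miss <- setdiff(p$layer, names(x))
    if (length(miss)) {
      nb_abort(sprintf("samples lack column(s): %s", paste(miss, collapse = ", ")),
               "mismatch")
    }
    out <- purrr::pmap(p, function(layer, min, max, ...) f(x[[layer]], min, max))
    out <- as_tibble(setNames(out, p$layer))
    new_samples(out, space = "standardized", cells = attr(x, "cells"),
                dropped = attr(x, "dropped"))
  } else if (is.numeric(x)) {
    if (nrow(p) != 1) {
      nb_abort("a numeric vector needs single-layer standardization params.",
               "mismatch")
    }
    f(x, p$min, p$max)
  } else {
    nb_abort("cannot standardize this object.", "type")
  }
}
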