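#' Fit a rectilinear niche envelope
#'
#' The envelope is the axis-aligned box spanned by the per-dimension minimum
#' and maximum of the occurrence samples (a single cluster: no partitioning of
#' points). Every fitting sample therefore lies inside the box and has
#' distance 0 — each occurrence cell is "maximally ecologically similar" by
#' construction, and no occurrence is ever discarded as an outlier.
#'
#' @param samples An `nb_samples` tibble / data frame with >= 1 row and no
#'   missing values.
#' @return An object of class `nb_envelope`: tibble with columns `dimension`,
#'   `lo`, `hi`; attribute `space` records the value space the envelope was
#'   fitted in (`raw`, `standardized` or `pca`).
#' @examples
#' env <- envelope_fit(data.frame(a = c(1, 5, 3), b = c(0, 2, 1)))
#' env
#' @export
envelope_fit <- function(samples) {
  m <- as.matrix(as.data.frame(samples))
  if (nrow(m) < 1) nb_abort("cannot fit an envelope to zero samples.", "empty")
  if (anyNA(m)) nb_abort("envelope input contains missing values.", "empty")
  out <- tibble(
    dimension = colnames(m) %||% paste0("V", seq_len(ncol(m))),
    lo = unname(apply(m, 2, min)),
    hi = unname(apply(m, 2, max))
  )
  attr(out, "space") <- sample_space(samples)
  class(out) <- c("nb_envelope", class(out))
  out
}

#' Per-dimension range distance
#'
#' Distance from a value to a closed interval: 0 inside `[lo, hi]`, otherwise
#' the distance to the nearer endpoint, `min(|v - lo|, |v - hi|)`. Vectorized
#' over all three arguments.
#'
#' @param v Numeric values.
#' @param lo,hi Interval bounds, `hi >= lo`.
#' @return Nonnegative numeric vector, `NA` where `v` is `NA`.
#' @examples
#' range_distance(c(50, 20, 95), 30, 70)  # 0, 10, 25
#' @export
range_distance <- function(v, lo, hi) {
  if (any(hi < lo)) nb_abort("`hi` must be >= `lo`.", "envelope")
  ifelse(v >= lo & v <= hi, 0, pmin(abs(v - lo), abs(v - hi)))
}

#' Euclidean distance from points to the envelope
#'
#' Aggregates the per-dimension [range_distance()] values into a single
#' distance per point: `sqrt(sum_j d_j^2)` (the Euclidean distance from the
#' point to the axis-aligned box; 0 exactly when the point is inside in every
#' dimension). `aggregate = "sumsq"` instead returns the raw sum of squares
#' `sum_j d_j^2`, the per-point term of the training error bookkeeping.
#'
#' @param p Numeric vector (one point), or matrix / data frame with one point
#'   per row; column count must equal the envelope dimension.
#' @param env An [envelope_fit()] result.
#' @param aggregate `"euclidean"` (default) or `"sumsq"`.
#' @return Numeric vector of distances, one per point.
#' @export
envelope_distance <- function(p, env, aggregate = c("euclidean", "sumsq")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(env, "nb_envelope"))
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  m <- as.matrix(p)
  if (ncol(m) != nrow(env)) {
    nb_abort(sprintf("dimension mismatch: envelope has %d dimensions, points have %d.",
                     nrow(env), ncol(m)), "mismatch")
  }
  sp <- sample_space(p, default = attr(env, "space"))
  if (!is.null(attr(env, "space")) && !identical(sp, attr(env, "space"))) {
    nb_abort(sprintf("value-space mismatch: envelope is '%s', points are '%s'.",
                     attr(env, "space"), sp), "space")
  }
  d2 <- rep(0, nrow(m))
  for (j in seq_len(ncol(m))) {
    dj <- range_distance(m[, j], env$lo[j], env$hi[j])
    d2 <- d2 + dj * dj
  }
  if (aggregate == "euclidean") sqrt(d2) else d2
}

#' Training error of an envelope
#'
#' Sum over sample points of the squared envelope distance (single cluster).
#' For an envelope fitted on the same samples this is exactly 0: the fit
#' contains every training point.
#'
#' @inheritParams envelope_distance
#' @param samples Points, one per row.
#' @return A single nonnegative number.
#' @export
training_error <- function(samples, env) {
  sum(envelope_distance(samples, env, aggregate = "sumsq"))
}

#' @export
print.nb_envelope <- function(x, ...) {
  cat(sprintf("<nb_envelope> %d dimensions, space '%s'\n",
              nrow(x), attr(x, "space") %||% "?"))
  print(as_tibble(unclass_envelope(x)))
  invisible(x)
}

unclass_envelope <- function(x) {
  class(x) <- setdiff(class(x), "nb_envelope")
  x
}
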