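#' Principal component reduction of environmental layers
#'
#' Fits a PCA to the occurrence sample matrix to collapse collinear climate
#' variables into a few orthogonal scores, mirroring the common practice of
#' reducing 19+ bioclimatic layers before envelope fitting. Components are the
#' eigenvectors of the sample covariance of the centered data (no scaling),
#' ordered by eigenvalue. The number kept is either pinned with
#' `n_components` or chosen as the smallest count whose cumulative explained
#' variance reaches `variance_target` (default 0.95).
#'
#' @param samples An `nb_samples` tibble (raw space) with >= 2 rows and no
#'   missing values.
#' @param n_components Optional fixed number of components to keep.
#' @param variance_target Cumulative explained-variance fraction in (0, 1],
#'   used when `n_components` is `NULL`.
#' @return An object of class `nb_pca`: fields `center`, `loadings`
#'   (columns = components, orthonormal), `sdev`, `explained` (fractions,
#'   nonincreasing), `n_kept`, `layer_names`.
#' @export
pca_fit <- function(samples, n_components = NULL, variance_target = 0.95) {
  m <- as.matrix(as.data.frame(samples))
  if (nrow(m) < 2) nb_abort("PCA needs at least 2 sample rows.", "pca")
  if (anyNA(m)) nb_abort("PCA input contains missing values.", "pca")
  if (is.null(n_components)) {
    if (!is.numeric(variance_target) || variance_target <= 0 || variance_target > 1) {
      nb_abort("`variance_target` must lie in (0, 1].", "pca")
    }
  }
  fit <- prcomp(m, center = TRUE, scale. = FALSE)
  expl <- fit$sdev^2 / sum(fit$sdev^2)
  n_kept <- if (!is.null(n_components)) {
    if (n_components < 1 || n_components > ncol(fit$rotation)) {
      nb_abort("`n_components` out of range.", "pca")
    }
    as.integer(n_components)
  } else {
    as.integer(which(cumsum(expl) >= variance_target - 1e-12)[1])
  }
  structure(
    list(center = fit$center, loadings = fit$rotation, sdev = fit$sdev,
         explained = expl, n_kept = n_kept, layer_names = colnames(m)),
    class = "nb_pca"
  )
}

#' @export
print.nb_pca <- function(x, ...) {
  cat(sprintf("<nb_pca> %d layers -> %d components (%.1f%% variance retained)\n",
              length(x$layer_names), x$n_kept,
              100 * sum(x$explained[seq_len(x$n_kept)])))
  invisible(x)
}

#' Project samples or a raster stack onto fitted components
#'
#' Centers the data with the model's per-layer means and projects onto the
#' kept loadings. For a stack, nodata in any input layer propagates to every
#' score layer of that cell.
#'
#' @param x An `nb_samples` tibble or an [nb_stack()] whose layers match the
#'   model's `layer_names`.
#' @param model An [pca_fit()] result.
#' @return Scores in `"pca"` space: a tibble with columns `PC1..PCk`, or an
#'   [nb_stack()] of score layers.
#' @export
pca_transform <- function(x, model) {
  stopifnot(inherits(model, "nb_pca"))
  L <- model$loadings[, seq_len(model$n_kept), drop = FALSE]
  project <- function(m) {
    if (ncol(m) != length(model$layer_names)) {
      nb_abort(sprintf("dimension mismatch: model has %d layers, data has %d.",
                       length(model$layer_names), ncol(m)), "mismatch")
    }
    sc <- sweep(m, 2, model$center) %*% L
    colnames(sc) <- paste0("PC", seq_len(ncol(sc)))
    sc
  }
  if (inherits(x, "nb_stack")) {
    if (!identical(names(x), model$layer_names)) {
      nb_abort("stack layer names/order do not match the PCA model.", "mismatch")
    }
    m <- stack_matrix(x)
    bad <- rowSums(is.na(m)) > 0
    m[bad, ] <- 0  # placeholder; masked below
    sc <- project(m)
    sc[bad, ] <- NA
    matrix_to_stack(sc, x, names = colnames(sc), space = "pca")
  } else {
    m <- as.matrix(as.data.frame(x))
    sc <- project(m)
    new_samples(as_tibble(as.data.frame(sc)), space = "pca",
                cells = attr(x, "cells"), dropped = attr(x, "dropped"))
  }
}
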