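#' Fit the full envelope suitability model
#'
#' One call from occurrence records to a fitted model, following the standard
#' stage order: extract per-occurrence layer values, optionally reduce them by
#' PCA (`mode = "pca"`), linearly standardize each dimension to 0–100, and fit
#' the rectilinear envelope in the standardized space. `mode = "raw"` skips
#' PCA and standardizes the raw layers directly, which keeps the envelope
#' bounds interpretable in the units of each factor.
#'
#' @param stack Raw-space [nb_stack()] of environmental layers.
#' @param occ An `nb_occurrences` tibble.
#' @param mode `"raw"` or `"pca"`.
#' @param n_components,variance_target PCA retention controls (see
#'   [pca_fit()]); used only in `"pca"` mode.
#' @param dedup Collapse occurrence points sharing a cell? Default `TRUE`.
#' @return An object of class `nb_model`: fields `mode`, `layer_names`,
#'   `pca` (or `NULL`), `std` ([standardize_fit()] params), `envelope`
#'   (standardized space), `samples_raw` (raw-space sample tibble),
#'   `cells`, `dropped`.
#' @export
fit_envelope_model <- function(stack, occ, mode = c("raw", "pca"),
                               n_components = NULL, variance_target = 0.95,
                               dedup = TRUE) {
  mode <- match.arg(mode)
  samples_raw <- extract_values(stack, occ, dedup = dedup)
  samples <- samples_raw
  pca <- NULL
  if (mode == "pca") {
    pca <- pca_fit(samples_raw, n_components = n_components,
                   variance_target = variance_target)
    samples <- pca_transform(samples_raw, pca)
  }
  std <- standardize_fit(samples)
  samples_std <- standardize_apply(samples, std)
  env <- envelope_fit(samples_std)
  structure(
    list(mode = mode, layer_names = names(stack), pca = pca, std = std,
         envelope = env, samples_raw = samples_raw,
         cells = attr(samples_raw, "cells"),
         dropped = attr(samples_raw, "dropped")),
    class = "nb_model"
  )
}

#' @export
print.nb_model <- function(x, ...) {
  cat(sprintf("<nb_model> mode '%s', %d layers, %d occurrence cells\n",
              x$mode, length(x$layer_names), nrow(x$samples_raw)))
  if (!is.null(x$pca)) print(x$pca)
  print(x$envelope)
  invisible(x)
}

#' Transform a raw stack into a model's envelope space
#'
#' Applies the model's PCA (if any) and standardization to a raw-space stack,
#' producing score layers the fitted envelope can be evaluated on.
#'
#' @param stack Raw-space [nb_stack()] with the model's layers.
#' @param model An [fit_envelope_model()] result.
#' @return An [nb_stack()] in `"standardized"` space.
#' @export
model_space_stack <- function(stack, model) {
  stopifnot(inherits(model, "nb_model"))
  if (!identical(names(stack), model$layer_names)) {
    nb_abort("stack layers do not match the fitted model.", "mismatch")
  }
  s <- if (!is.null(model$pca)) pca_transform(stack, model$pca) else stack
  standardize_apply(s, model$std)
}

#' Predict the envelope-distance surface for a raw stack
#'
#' @inheritParams model_space_stack
#' @param aggregate `"euclidean"` or `"sumsq"`; see [envelope_distance()].
#' @return An [distance_surface()] result.
#' @export
predict_distance <- function(stack, model, aggregate = "euclidean") {
  distance_surface(model_space_stack(stack, model), model$envelope,
                   aggregate = aggregate)
}

#' Save / load a fitted model as a plain-text sidecar
#'
#' Serializes everything needed to reproduce predictions bit-for-bit — layer
#' names, mode, PCA center/loadings/explained variance, standardization
#' min/max and the envelope bounds — as YAML with full double precision
#' (doubles stored as hexadecimal float strings).
#'
#' @param model An [fit_envelope_model()] result.
#' @param path Output / input path (conventionally `model.yaml`).
#' @return `save_model()`: `path`, invisibly. `load_model()`: an `nb_model`
#'   (without the training sample tibble).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "nb_model"))
  num <- function(x) sprintf("%a", as.numeric(x))
  obj <- list(
    format = "nichebox-model-1",
    mode = model$mode,
    layer_names = as.list(model$layer_names),
    std = list(layer = as.list(model$std$layer),
               min = as.list(num(model$std$min)),
               max = as.list(num(model$std$max)),
               degenerate = as.list(model$std$degenerate),
               new_min = num(attr(model$std, "new_min")),
               new_max = num(attr(model$std, "new_max"))),
    envelope = list(dimension = as.list(model$envelope$dimension),
                    lo = as.list(num(model$envelope$lo)),
                    hi = as.list(num(model$envelope$hi)),
                    space = attr(model$envelope, "space"))
  )
  if (!is.null(model$pca)) {
    obj$pca <- list(center = as.list(num(model$pca$center)),
                    loadings = as.list(num(model$pca$loadings)),
                    n_layers = length(model$pca$layer_names),
                    sdev = as.list(num(model$pca$sdev)),
                    explained = as.list(num(model$pca$explained)),
                    n_kept = model$pca$n_kept,
                    layer_names = as.list(model$pca$layer_names))
  }
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(yaml::read_yaml(path), error = function(e) NULL)
  if (!is.list(obj) || !identical(obj$format, "nichebox-model-1")) {
    nb_abort(sprintf("'%s' is not a nichebox model sidecar.", path), "format")
  }
  num <- function(x) vapply(unlist(x), function(s) as.numeric(s), numeric(1),
                            USE.NAMES = FALSE)
  std <- tibble(layer = unlist(obj$std$layer), min = num(obj$std$min),
                max = num(obj$std$max), degenerate = unlist(obj$std$degenerate))
  attr(std, "new_min") <- num(obj$std$new_min)
  attr(std, "new_max") <- num(obj$std$new_max)
  class(std) <- c("nb_standardization", class(std))
  env <- tibble(dimension = unlist(obj$envelope$dimension),
                lo = num(obj$envelope$lo), hi = num(obj$envelope$hi))
  attr(env, "space") <- obj$envelope$space
  class(env) <- c("nb_envelope", class(env))
  pca <- NULL
  if (!is.null(obj$pca)) {
    p <- obj$pca$n_layers
    pca <- structure(
      list(center = setNames(num(obj$pca$center), unlist(obj$pca$layer_names)),
           loadings = matrix(num(obj$pca$loadings), nrow = p),
           sdev = num(obj$pca$sdev), explained = num(obj$pca$explained),
           n_kept = as.integer(obj$pca$n_kept),
           layer_names = unlist(obj$pca$layer_names)),
      class = "nb_pca")
    rownames(pca$loadings) <- pca$layer_names
    colnames(pca$loadings) <- paste0("PC", seq_len(ncol(pca$loadings)))
  }
  structure(
    list(mode = obj$mode, layer_names = unlist(obj$layer_names), pca = pca,
         std = std, envelope = env, samples_raw = NULL, cells = NULL,
         dropped = NULL),
    class = "nb_model"
  )
}
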