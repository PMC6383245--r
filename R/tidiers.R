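#' Tidy and glance methods
#'
#' Broom-style summaries: `tidy()` returns one row per model term (envelope
#' dimension, principal component, standardization layer), `glance()` a
#' one-row model summary.
#'
#' @param x An `nb_envelope`, `nb_pca`, `nb_model` or `nb_standardization`.
#' @param ... Unused.
#' @return A tibble.
#' @name nichebox-tidiers
NULL

#' @rdname nichebox-tidiers
#' @method tidy nb_envelope
#' @export
tidy.nb_envelope <- function(x, ...) {
  out <- as_tibble(unclass_envelope(x))
  out$width <- out$hi - out$lo
  out
}

#' @rdname nichebox-tidiers
#' @method glance nb_envelope
#' @export
glance.nb_envelope <- function(x, ...) {
  tibble(n_dimensions = nrow(x), space = attr(x, "space") %||% NA_character_,
         total_width = sum(x$hi - x$lo))
}

#' @rdname nichebox-tidiers
#' @method tidy nb_pca
#' @export
tidy.nb_pca <- function(x, ...) {
  tibble(component = paste0("PC", seq_along(x$explained)),
         std_dev = x$sdev,
         explained_variance = x$explained,
         cumulative_variance = cumsum(x$explained),
         kept = seq_along(x$explained) <= x$n_kept)
}

#' @rdname nichebox-tidiers
#' @method glance nb_pca
#' @export
glance.nb_pca <- function(x, ...) {
  tibble(n_layers = length(x$layer_names), n_kept = x$n_kept,
         variance_retained = sum(x$explained[seq_len(x$n_kept)]))
}

#' @rdname nichebox-tidiers
#' @method tidy nb_standardization
#' @export
tidy.nb_standardization <- function(x, ...) {
  as_tibble(unclass(x)[c("layer", "min", "max", "degenerate")])
}

#' @rdname nichebox-tidiers
#' @method tidy nb_model
#' @export
tidy.nb_model <- function(x, ...) {
  env <- tidy(x$envelope)
  env$space <- attr(x$envelope, "space") %||% NA_character_
  env
}

#' @rdname nichebox-tidiers
#' @method glance nb_model
#' @export
glance.nb_model <- function(x, ...) {
  tibble(
    mode = x$mode,
    n_layers = length(x$layer_names),
    n_dimensions = nrow(x$envelope),
    n_occurrence_cells = if (!is.null(x$samples_raw)) nrow(x$samples_raw) else NA_integer_,
    n_dropped = if (!is.null(x$dropped)) sum(x$dropped) else NA_integer_,
    training_error = if (!is.null(x$samples_raw)) {
      s <- if (!is.null(x$pca)) pca_transform(x$samples_raw, x$pca) else x$samples_raw
      training_error(standardize_apply(s, x$std), x$envelope)
    } else NA_real_
  )
}
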