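# Plausible per-factor value ranges used to rescale smoothed noise fields so
# synthetic layers carry bioclim-like units (temperature degC, precipitation mm,
# radiation kJ m-2 day-1, vapour pressure kPa, ...). Recycled past 6 factors.
factor_palette <- list(
  c(-5, 30),      # annual mean temperature, degC
  c(0, 3000),     # annual precipitation, mm
  c(0, 100),      # seasonality index
  c(5000, 22000), # solar radiation, kJ m-2 day-1
  c(0.2, 3.5),    # water vapour pressure, kPa
  c(-20, 15)      # min temperature of coldest month, degC
)

# separable Gaussian blur via row/col band-matrix products; sigma in cells
blur_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  k <- outer(seq_len(n), seq_len(n), function(i, j) dnorm(j - i, sd = sigma))
  k / rowSums(k)
}

#' Generate a synthetic multi-factor landscape
#'
#' Builds `n_factors` spatially autocorrelated continuous layers by Gaussian
#' smoothing of white noise (length scale `smoothness`, in cells; 0 gives
#' independent per-cell noise) and rescaling each layer to a plausible
#' bioclimatic unit range. Deterministic given `seed`; a simple WGS84
#' georeference is attached. Used to validate the whole pipeline against a
#' known ground truth without any data download.
#'
#' @param n_factors Number of layers (>= 1).
#' @param shape Integer vector `c(rows, cols)`.
#' @param smoothness Gaussian smoothing length scale in cells (>= 0).
#' @param seed Integer random seed; all randomness is local to the call.
#' @param xll,yll,cellsize,crs Georeference of the generated layers.
#' @return An [nb_stack()] of layers named `BIO1..BIOn`, raw space.
#' @export
make_landscape <- function(n_factors = 6, shape = c(200, 200), smoothness = 5,
                           seed = 1, xll = -5, yll = 40, cellsize = 1 / 120,
                           crs = "EPSG:4326") {
  if (n_factors < 1) nb_abort("`n_factors` must be >= 1.", "synth")
  if (length(shape) != 2 || any(shape < 1)) {
    nb_abort("`shape` must be two positive integers.", "synth")
  }
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  A <- blur_matrix(nr, smoothness)
  B <- blur_matrix(nc, smoothness)
  layers <- withr::with_seed(seed, {
    lapply(seq_len(n_factors), function(j) {
      z <- A %*% matrix(stats::rnorm(nr * nc), nr, nc) %*% t(B)
      rng <- factor_palette[[(j - 1) %% length(factor_palette) + 1]]
      lo <- min(z); hi <- max(z)
      v <- if (hi > lo) (z - lo) / (hi - lo) * diff(rng) + rng[1] else
        matrix(mean(rng), nr, nc)
      nb_grid(v, xll = xll, yll = yll, cellsize = cellsize, crs = crs,
              kind = "continuous")
    })
  })
  nb_stack(layers, names = paste0("BIO", seq_len(n_factors)), space = "raw")
}

#' Generate a synthetic categorical soil layer
#'
#' Contiguous patches of integer codes `1..n_classes`, built as the nearest-
#' seed (Voronoi) partition of randomly placed seed points; the first
#' `n_classes` seeds carry one code each, so every code appears. Deterministic
#' given `seed`.
#'
#' @inheritParams make_landscape
#' @param n_classes Number of soil classes (>= 2).
#' @param n_patches Number of Voronoi seed points (defaults to roughly one
#'   per 400 cells, at least `n_classes`).
#' @return A categorical [nb_grid()].
#' @export
make_soil <- function(shape = c(200, 200), n_classes = 6, seed = 1,
                      n_patches = NULL, xll = -5, yll = 40, cellsize = 1 / 120,
                      crs = "EPSG:4326") {
  if (n_classes < 2) nb_abort("`n_classes` must be >= 2.", "synth")
  if (length(shape) != 2 || any(shape < 1)) {
    nb_abort("`shape` must be two positive integers.", "synth")
  }
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  n_patches <- n_patches %||% max(n_classes, round(nr * nc / 400))
  withr::with_seed(seed, {
    sr <- stats::runif(n_patches, 0.5, nr + 0.5)
    sc <- stats::runif(n_patches, 0.5, nc + 0.5)
    code <- c(seq_len(n_classes),
              sample.int(n_classes, max(0, n_patches - n_classes), replace = TRUE))
  })
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  best <- matrix(Inf, nr, nc)
  cls <- matrix(1L, nr, nc)
  for (s in seq_len(n_patches)) {
    d2 <- (rows - sr[s])^2 + (cols - sc[s])^2
    better <- d2 < best
    best[better] <- d2[better]
    cls[better] <- code[s]
  }
  nb_grid(cls * 1.0, xll = xll, yll = yll, cellsize = cellsize, crs = crs,
          kind = "categorical")
}

#' Assemble the synthetic ground truth
#'
#' The true suitability mask is 1 exactly where every factor lies inside the
#' true raw-space envelope **and** the soil code belongs to the suitable set —
#' the same rule the fitted pipeline tries to recover.
#'
#' @param stack Raw-space factor [nb_stack()].
#' @param soil Categorical soil [nb_grid()], aligned with `stack`.
#' @param true_envelope An [envelope_fit()]-style envelope in raw space, with
#'   one row per stack layer.
#' @param suitable_codes Vector (or `nb_soil_classes`) of suitable soil codes.
#' @return An object of class `nb_truth`: fields `true_envelope`,
#'   `suitable_codes`, `true_mask` (binary [nb_grid()]), `stack`, `soil`.
#' @export
make_truth <- function(stack, soil, true_envelope, suitable_codes) {
  stopifnot(inherits(stack, "nb_stack"), inherits(soil, "nb_grid"),
            inherits(true_envelope, "nb_envelope"))
  assert_aligned(stack)
  if (!same_geometry(stack$layers[[1]], soil)) {
    nb_abort("soil grid is not aligned with the factor stack.", "misaligned")
  }
  if (nrow(true_envelope) != length(stack)) {
    nb_abort("envelope dimension does not match the stack.", "mismatch")
  }
  codes <- if (is.data.frame(suitable_codes)) suitable_codes$code else suitable_codes
  m <- stack_matrix(stack)
  inside <- rep(TRUE, nrow(m))
  for (j in seq_len(ncol(m))) {
    inside <- inside & m[, j] >= true_envelope$lo[j] & m[, j] <= true_envelope$hi[j]
  }
  soil_ok <- as.vector(soil$values) %in% codes
  mask <- as.numeric(inside & soil_ok)
  mask[is.na(inside) | is.na(as.vector(soil$values))] <- NA
  g0 <- stack$layers[[1]]
  structure(
    list(true_envelope = true_envelope, suitable_codes = codes,
         true_mask = new_mask(matrix(mask, nrow(g0$values)), g0),
         stack = stack, soil = soil),
    class = "nb_truth"
  )
}

#' Convenience true envelope from layer quantiles
#'
#' Builds a raw-space envelope whose per-layer bounds are the given quantiles
#' of each layer's unmasked values — a simple way to carve a known suitable
#' box out of a synthetic landscape.
#'
#' @param stack A raw-space [nb_stack()].
#' @param lower,upper Quantile probabilities for the bounds.
#' @return An `nb_envelope` in raw space.
#' @export
quantile_envelope <- function(stack, lower = 0.25, upper = 0.75) {
  stopifnot(inherits(stack, "nb_stack"))
  rows <- purrr::imap(stack$layers, function(g, nm) {
    q <- stats::quantile(g$values, c(lower, upper), na.rm = TRUE, names = FALSE)
    tibble(dimension = nm, lo = q[1], hi = q[2])
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "space") <- "raw"
  class(out) <- c("nb_envelope", class(out))
  out
}

#' Sample occurrence points from the truth mask
#'
#' Draws `n` cells uniformly without replacement from the `true_mask = 1`
#' cells (with replacement, and a warning, if `n` exceeds their number) and
#' returns their cell-center coordinates as an occurrence set. Sampling is
#' noiseless: every generated point lies in the truly suitable region, since
#' the envelope model has no outlier-rejection mechanism and every point
#' shapes the fit.
#'
#' @param truth An [make_truth()] result.
#' @param n Number of points (>= 1).
#' @param seed Integer random seed.
#' @param species Species label attached to the points.
#' @return An `nb_occurrences` tibble with attribute `cells`.
#' @export
sample_occurrences <- function(truth, n, seed = 1, species = "synthetic") {
  stopifnot(inherits(truth, "nb_truth"))
  if (n < 1) nb_abort("`n` must be >= 1.", "synth")
  mv <- truth$true_mask$values
  suitable <- which(mv == 1)  # column-major cell indices
  if (length(suitable) == 0) {
    nb_abort("truth mask has no suitable cells to sample from.", "empty")
  }
  replace <- n > length(suitable)
  if (replace) {
    nb_warn(sprintf("requested %d points but only %d suitable cells; sampling with replacement.",
                    n, length(suitable)), "oversample")
  }
  idx <- withr::with_seed(seed, {
    if (replace) sample(suitable, n, replace = TRUE) else sample(suitable, n)
  })
  row <- ((idx - 1L) %% nrow(mv)) + 1L
  col <- ((idx - 1L) %/% nrow(mv)) + 1L
  xy <- cell_center(truth$true_mask, row, col)
  occ <- as_occurrences(tibble(species = species,
                               longitude = xy$longitude,
                               latitude = xy$latitude))
  attr(occ, "cells") <- tibble(row = row, col = col)
  occ
}

#' Write a complete synthetic fixture bundle
#'
#' Generates a landscape, soil layer, truth mask and occurrence sample, and
#' writes everything a pipeline run needs to `dir`: one `.asc` per factor,
#' `soil.asc`, `truth.asc`, `occurrences.csv`, `manifest.csv` and a ready
#' `config.yaml` pointing at them.
#'
#' @inheritParams make_landscape
#' @param dir Output directory (created if missing).
#' @param n_occurrences Number of occurrence points to sample.
#' @param n_soil_classes Number of soil classes.
#' @param suitable_codes Soil codes forming the truly suitable set.
#' @param envelope_quantiles Lower/upper quantiles of the true envelope.
#' @param mode Pipeline mode written into the config (`"raw"` or `"pca"`).
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
write_fixture_bundle <- function(dir, n_factors = 6, shape = c(60, 60),
                                 smoothness = 4, n_occurrences = 50,
                                 n_soil_classes = 5, suitable_codes = c(1, 2, 3),
                                 envelope_quantiles = c(0.25, 0.75),
                                 mode = "raw", seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stack <- make_landscape(n_factors, shape, smoothness, seed = seed)
  soil <- make_soil(shape, n_soil_classes, seed = seed + 1)
  env <- quantile_envelope(stack, envelope_quantiles[1], envelope_quantiles[2])
  truth <- make_truth(stack, soil, env, suitable_codes)
  occ <- sample_occurrences(truth, n_occurrences, seed = seed + 2)
  paths <- purrr::imap_chr(stack$layers, function(g, nm) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_raster(g, p)
    p
  })
  write_raster(soil, file.path(dir, "soil.asc"))
  write_raster(truth$true_mask, file.path(dir, "truth.asc"))
  readr::write_csv(as_tibble(occ), file.path(dir, "occurrences.csv"))
  manifest <- tibble(name = names(stack), path = paste0(names(stack), ".asc"),
                     kind = "continuous")
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  config <- list(
    manifest = "manifest.csv",
    occurrences = "occurrences.csv",
    mode = mode,
    pca = list(variance_target = 0.95),
    classes = list(n_classes = 5, suitable = 0L),
    soil = list(raster = "soil.asc", attribute_filter = FALSE),
    dedup = TRUE,
    out_dir = "out"
  )
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  invisible(list(stack = stack, soil = soil, truth = truth, occurrences = occ,
                 dir = dir, config = file.path(dir, "config.yaml")))
}
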