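#' Run the full suitability pipeline from a configuration file
#'
#' Executes, in order: ingest layers and occurrences, extract per-occurrence
#' values, optional PCA, standardization, envelope fit, distance surface,
#' classification, soil masking, overlay intersection, and reporting. Every
#' artifact is written to `out_dir`; identical config and inputs give
#' bit-identical text outputs. Any stage failure aborts with the stage name
#' and cause.
#'
#' Config keys (YAML or a named list): `manifest`, `occurrences`, `mode`
#' (`"raw"`/`"pca"`), `pca:` (`n_components` or `variance_target`), `classes:`
#' (`n_classes`, optional `breaks`, `suitable` class ids), `soil:` (`raster`,
#' optional `labels` CSV, optional `attribute_manifest` +
#' `attribute_filter: true`), `dedup`, `out_dir`. Relative paths resolve
#' against the config file's directory.
#'
#' @param config Path to a YAML config file, or an equivalent named list (in
#'   which case relative paths resolve against `base_dir`).
#' @param base_dir Base directory for relative paths when `config` is a list.
#' @return Invisibly, a list with the fitted `model`, `surface`, `classes`,
#'   masks, report tibbles and the output file `paths`.
#' @export
run_pipeline <- function(config, base_dir = ".") {
  if (is.character(config)) {
    if (!file.exists(config)) {
      nb_abort(sprintf("config file not found: '%s'", config), "read")
    }
    base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    inform(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      nb_abort(sprintf("pipeline stage '%s' failed: %s", name,
                       conditionMessage(e)), "stage")
    })
  }

  out_dir <- resolve(config$out_dir %||% "out")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stack <- stage("ingest", {
    if (is.null(config$manifest)) nb_abort("config lacks `manifest`.", "config")
    read_stack(resolve(config$manifest))
  })
  occ <- stage("ingest", {
    if (is.null(config$occurrences)) nb_abort("config lacks `occurrences`.", "config")
    read_occurrences(resolve(config$occurrences))
  })
  say("ingest: %d layers (%s), %d occurrence points", length(stack),
      paste(names(stack), collapse = ", "), nrow(occ))

  mode <- config$mode %||% "raw"
  model <- stage("fit", {
    fit_envelope_model(stack, occ, mode = mode,
                       n_components = config$pca$n_components,
                       variance_target = config$pca$variance_target %||% 0.95,
                       dedup = config$dedup %||% TRUE)
  })
  say("fit: mode '%s', %d occurrence cells retained (%d dropped)",
      model$mode, nrow(model$samples_raw), sum(model$dropped))
  if (!is.null(model$pca)) {
    say("fit: PCA kept %d of %d components (%.1f%% variance)",
        model$pca$n_kept, length(model$pca$layer_names),
        100 * sum(model$pca$explained[seq_len(model$pca$n_kept)]))
  }

  surface <- stage("distance", predict_distance(stack, model))
  say("distance: range [%g, %g]", surface$min_d, surface$max_d)

  classes_cfg <- config$classes %||% list()
  suit_map <- stage("classify", {
    classify_distance(surface,
                      n_classes = classes_cfg$n_classes %||% 5,
                      breaks = classes_cfg$breaks)
  })
  say("classify: %d classes, breaks %s", suit_map$n_classes,
      paste(format(suit_map$breaks, digits = 6), collapse = ", "))

  suitable_ids <- as.integer(classes_cfg$suitable %||% 0L)
  cmask <- stage("climate_mask", climate_mask(suit_map, suitable_ids))

  smask <- NULL; soil_classes <- NULL; final <- cmask
  if (!is.null(config$soil$raster)) {
    soil_grid <- stage("soil", read_raster(resolve(config$soil$raster),
                                           kind = "categorical"))
    labels <- NULL
    if (!is.null(config$soil$labels)) {
      lab <- readr::read_csv(resolve(config$soil$labels),
                             show_col_types = FALSE, progress = FALSE)
      labels <- setNames(as.character(lab$name), lab$code)
    }
    soil_classes <- stage("soil", suitable_soil_classes(soil_grid, model$cells,
                                                        labels = labels))
    say("soil: %d suitable class(es): %s", nrow(soil_classes),
        paste(soil_classes$code, collapse = ", "))
    smask <- stage("soil", soil_mask(soil_grid, soil_classes))
    if (isTRUE(config$soil$attribute_filter) &&
        !is.null(config$soil$attribute_manifest)) {
      attr_stack <- stage("soil", read_stack(resolve(config$soil$attribute_manifest)))
      amask <- stage("soil", attribute_filter(attr_stack, model$cells))
      smask <- stage("soil", intersect_masks(smask, amask))
      say("soil: attribute filter applied over %d attribute layer(s)",
          length(attr_stack))
    }
    final <- stage("overlay", intersect_masks(cmask, smask))
  }

  rt <- stage("report", range_table(model$samples_raw))
  areas <- stage("report", area_summary(suit_map))
  final_area <- stage("report", area_summary(final))
  say("report: final suitable area %.2f km^2 over %d cell(s)",
      sum(final_area$area_km2[final_area$class == 1], 0),
      sum(final_area$n_cells[final_area$class == 1], 0))

  paths <- list(
    distance = file.path(out_dir, "distance.asc"),
    classes = file.path(out_dir, "classes.asc"),
    suitable = file.path(out_dir, "suitable.asc"),
    range_table = file.path(out_dir, "range_table.csv"),
    area_summary = file.path(out_dir, "area_summary.csv"),
    final_area = file.path(out_dir, "final_area.csv"),
    samples = file.path(out_dir, "samples.csv"),
    model = file.path(out_dir, "model.yaml"),
    log = file.path(out_dir, "run.log")
  )
  stage("write", {
    write_raster(surface$grid, paths$distance)
    write_raster(suit_map$grid, paths$classes)
    write_raster(final, paths$suitable)
    readr::write_csv(rt, paths$range_table)
    readr::write_csv(areas, paths$area_summary)
    readr::write_csv(final_area, paths$final_area)
    # raw per-factor samples, long format, for distribution plots
    readr::write_csv(
      tidyr::pivot_longer(as_tibble(as.data.frame(model$samples_raw)),
                          dplyr::everything(),
                          names_to = "factor", values_to = "value"),
      paths$samples)
    save_model(model, paths$model)
    writeLines(log_lines, paths$log)
  })
  say("wrote %d artifacts to %s", length(paths), out_dir)

  invisible(list(model = model, surface = surface, classes = suit_map,
                 climate_mask = cmask, soil_mask = smask,
                 soil_classes = soil_classes, final_mask = final,
                 range_table = rt, area_summary = areas,
                 final_area = final_area, paths = paths))
}
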