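#' Pipeline run configuration
#'
#' Bundles the user-set parameters of the whole chain. The defaults are the
#' working values for 8-bit, 120 px single-cell crops: local-maximum radius
#' 3 px, minimum object area 3 px, per-pixel intensity floor 1.1 times the
#' nucleus mean, top-hat structuring element of 10 px diameter (larger than
#' a small focus), and a quality gate of mean channel Pearson > 0.4 with a
#' pronounced (>= 10% deep) histogram valley.
#'
#' @param local_max_radius_px Local-maximum search radius (px).
#' @param min_object_area_px Minimum object area (px).
#' @param pixel_intensity_factor Per-pixel floor as a multiple of the
#'   nucleus mean intensity.
#' @param tophat_diameter_px Top-hat structuring-element diameter (px).
#' @param crop_size_px Single-cell crop side (px).
#' @param bit_depth Grey-value bit depth of the input images.
#' @param hist_bins,hist_smooth Score-histogram bins and smoothing window.
#' @param step_decay Geometric step decay of the threshold-adjustment loop.
#' @param max_iter Iteration cap of the adjustment loop.
#' @param sd_frac Stop rule of the adjustment loop (sd of the trailing six
#'   foci-per-cell values below this fraction of their mean).
#' @param pearson_min Minimum acceptable mean channel correlation.
#' @param valley_prominence Required relative depth of the histogram valley.
#' @param gate_k G1-gate width in robust deviations.
#' @param min_gate_cells Minimum cells required to fit the G1 gate.
#' @param seg_min_area,seg_max_area,seg_blur_sigma Nucleus segmentation
#'   parameters.
#' @param rng_seed Seed recorded with the run.
#' @return Object of class `run_config`.
#' @export
run_config <- function(local_max_radius_px = 3,
                       min_object_area_px = 3,
                       pixel_intensity_factor = 1.1,
                       tophat_diameter_px = 10,
                       crop_size_px = 120,
                       bit_depth = 8,
                       hist_bins = 60,
                       hist_smooth = 5,
                       step_decay = 0.8,
                       max_iter = 60,
                       sd_frac = 0.05,
                       pearson_min = 0.4,
                       valley_prominence = 0.1,
                       gate_k = 2.5,
                       min_gate_cells = 10,
                       seg_min_area = 300,
                       seg_max_area = 10000,
                       seg_blur_sigma = 3,
                       rng_seed = 1L) {
  cfg <- list(local_max_radius_px = local_max_radius_px,
              min_object_area_px = min_object_area_px,
              pixel_intensity_factor = pixel_intensity_factor,
              tophat_diameter_px = tophat_diameter_px,
              crop_size_px = crop_size_px, bit_depth = bit_depth,
              hist_bins = hist_bins, hist_smooth = hist_smooth,
              step_decay = step_decay, max_iter = max_iter, sd_frac = sd_frac,
              pearson_min = pearson_min, valley_prominence = valley_prominence,
              gate_k = gate_k, min_gate_cells = min_gate_cells,
              seg_min_area = seg_min_area, seg_max_area = seg_max_area,
              seg_blur_sigma = seg_blur_sigma, rng_seed = as.integer(rng_seed))
  stopifnot(cfg$local_max_radius_px >= 1, cfg$min_object_area_px >= 1,
            cfg$pixel_intensity_factor > 0, cfg$tophat_diameter_px >= 3,
            cfg$crop_size_px >= 16)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> radius", x$local_max_radius_px, "px; min area",
      x$min_object_area_px, "px; floor", x$pixel_intensity_factor,
      "x I_nucl; top-hat", x$tophat_diameter_px, "px; crop",
      x$crop_size_px, "px\n")
  invisible(x)
}

#' Run the full foci-quantification pipeline
#'
#' Chains every stage over a set of fields: nucleus segmentation, single-cell
#' cropping with best-plane selection, G1 gating, object detection and
#' scoring, channel-correlation and histogram quality gating, automated
#' start-threshold estimation, optional rater-in-the-loop adjustment, and the
#' foci-per-cell count. Deterministic given the inputs and configuration.
#'
#' @param fields A list of [field_image()] objects, a single `field_image`,
#'   or a directory path containing multi-page field TIFFs.
#' @param config A [run_config()].
#' @param oracle Optional rating callback for [adjust_threshold()]; when
#'   `NULL`, the automated start threshold is used as the final threshold.
#' @param output_dir Optional directory: writes `cells.csv`, `objects.csv`,
#'   `quality.json`, `session.json` (when an oracle ran), `results.json` and
#'   the resolved `config.yaml`.
#' @return Object of class `foci_run`: list with `cells` (gated manifest),
#'   `objects` (scored objects of retained cells), `pearson`, `quality`,
#'   `start`, `session` (or `NULL`), `foci_per_cell`, `threshold`
#'   (linear scale), `n_cells`, `dropped` and `config`.
#' @export
run_pipeline <- function(fields, config = run_config(), oracle = NULL,
                         output_dir = NULL) {
  if (inherits(fields, "field_image")) fields <- list(fields)
  if (is.character(fields)) {
    paths <- sort(list.files(fields, pattern = "\\.tiff?$", full.names = TRUE))
    if (length(paths) == 0) {
      warn("No TIFF fields found in input directory; empty result.")
    }
    fields <- list()
    for (p in paths) {
      f <- tryCatch(read_field(p), error = function(e) {
        warn(sprintf("Skipping unreadable field %s: %s", p, conditionMessage(e)))
        NULL
      })
      if (!is.null(f)) fields[[length(fields) + 1]] <- f
    }
  }

  all_cells <- list(); dropped <- list()
  for (fi in seq_along(fields)) {
    field <- fields[[fi]]
    labels <- segment_nuclei(field$dapi, min_area = config$seg_min_area,
                             max_area = config$seg_max_area,
                             blur_sigma = config$seg_blur_sigma)
    cells <- crop_cells(field, labels, crop_size = config$crop_size_px)
    dr <- attr(cells, "dropped")
    if (nrow(dr) > 0) dropped[[length(dropped) + 1]] <-
        dplyr::mutate(dr, field = fi)
    for (cl in cells) {
      cl$field <- fi
      cl$id <- cl$id + 10000L * fi  # field-unique cell ids
      all_cells[[length(all_cells) + 1]] <- cl
    }
  }
  dropped <- if (length(dropped)) dplyr::bind_rows(dropped) else
    tibble(label = integer(), reason = character(), field = integer())

  empty <- list(cells = tibble(), objects = tibble(), pearson = NULL,
                quality = NULL, start = NULL, session = NULL,
                foci_per_cell = NA_real_, threshold = NA_real_,
                n_cells = 0L, dropped = dropped, config = config)
  if (length(all_cells) == 0) {
    warn("No analyzable cells found.")
    return(structure(empty, class = "foci_run"))
  }

  manifest <- filter_g1(cells_manifest(all_cells), k = config$gate_k,
                        min_cells = config$min_gate_cells)
  retained_flag <- manifest$retained
  retained_flag[is.na(retained_flag)] <- TRUE  # ungated: keep everything
  kept <- all_cells[retained_flag]
  n_cells <- length(kept)
  if (n_cells == 0) {
    warn("G1 gate removed every cell.")
    out <- empty; out$cells <- manifest
    return(structure(out, class = "foci_run"))
  }

  objects <- score_cells(kept, config)
  pear <- sample_pearson(kept)
  hist <- tryCatch(oep_histogram(objects$oep, "log", bins = config$hist_bins,
                                 smooth = config$hist_smooth),
                   error = function(e) NULL)
  quality <- if (is.null(hist)) {
    structure(list(pass = FALSE, reasons = "no_histogram_minimum",
                   mean_pearson = pear$mean_pearson,
                   pearson_min = config$pearson_min,
                   bimodality = list(bimodal = FALSE, mode_mids = numeric(0),
                                     valley_mid = NA_real_,
                                     valley_depth_frac = NA_real_)),
              class = "quality_check")
  } else {
    sample_quality(pear$mean_pearson, hist, pearson_min = config$pearson_min,
                   prominence = config$valley_prominence)
  }

  start <- tryCatch(estimate_start_threshold(objects$oep),
                    error = function(e) NULL)
  session <- NULL
  if (!is.null(start) && !is.null(oracle)) {
    session <- adjust_threshold(objects, n_cells, oracle, start = start,
                                decay = config$step_decay,
                                sd_frac = config$sd_frac,
                                max_iter = config$max_iter,
                                bins = config$hist_bins)
  }
  threshold <- if (!is.null(session)) 10^session$final_log_threshold
    else if (!is.null(start)) start$threshold else NA_real_
  fpc <- if (!is.null(session)) session$final_foci_per_cell
    else if (is.finite(threshold)) count_foci(objects, threshold, n_cells)
    else NA_real_

  run <- structure(list(cells = manifest, objects = objects, pearson = pear,
                        quality = quality, start = start, session = session,
                        foci_per_cell = fpc, threshold = threshold,
                        n_cells = n_cells, dropped = dropped, config = config),
                   class = "foci_run")
  if (!is.null(output_dir)) write_run(run, output_dir)
  run
}

#' @export
print.foci_run <- function(x, ...) {
  cat("<foci_run>", x$n_cells, "analyzed cells,", nrow(x$objects), "objects;",
      "foci/cell =", format(x$foci_per_cell, digits = 4), "\n")
  if (!is.null(x$quality)) print(x$quality)
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x A `foci_run`.
#' @param ... Unused.
#' @return Tibble with cell/object counts, threshold, foci per cell and the
#'   quality verdict ("discard" when the gate failed).
#' @method glance foci_run
#' @export
glance.foci_run <- function(x, ...) {
  tibble(n_cells = x$n_cells, n_objects = nrow(x$objects),
         threshold = x$threshold, foci_per_cell = x$foci_per_cell,
         mean_pearson = if (is.null(x$pearson)) NA_real_ else
           x$pearson$mean_pearson,
         verdict = if (is.null(x$quality) || x$quality$pass) "ok" else "discard")
}

write_run <- function(run, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  write_table_csv(run$cells, file.path(output_dir, "cells.csv"))
  write_table_csv(run$objects, file.path(output_dir, "objects.csv"))
  if (!is.null(run$quality)) {
    jsonlite::write_json(glance(run$quality), file.path(output_dir, "quality.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  if (!is.null(run$session)) {
    jsonlite::write_json(
      list(glance = glance(run$session), history = tidy(run$session)),
      file.path(output_dir, "session.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  jsonlite::write_json(glance(run), file.path(output_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write_config_yaml(run$config, file.path(output_dir, "config.yaml"))
  invisible(output_dir)
}
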