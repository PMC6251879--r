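# Fixture builders shared across test files.

# Gaussian blob added to a matrix (independent of the package's renderer).
fx_blob <- function(img, row, col, amp, sigma) {
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    img[r, c] <- img[r, c] + amp * exp(-((r - row)^2 + (c - col)^2) / (2 * sigma^2))
  }
  img
}

fx_disc_mask <- function(n, row, col, radius) {
  outer(seq_len(n), seq_len(n), function(r, c) (r - row)^2 + (c - col)^2 <= radius^2)
}

# Build a cell_image directly from matrices (bypasses cropping) so OEP-level
# behaviour can be tested on exact, un-quantized images.
fx_cell <- function(red, green, mask = NULL, id = 1L, dapi = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(red), ncol(red))
  if (is.null(dapi)) dapi <- matrix(100, nrow(red), ncol(red))
  rs <- array(rep(red, 5), c(dim(red), 5))
  gs <- array(rep(green, 5), c(dim(green), 5))
  structure(list(
    id = id, origin = c(row = 0, col = 0), mask = mask, dapi = dapi,
    red_stack = rs, green_stack = gs, best_red = 1L, best_green = 1L,
    red = red, green = green,
    stats = list(i_nucl_red = mean(red[mask]), i_nucl_green = mean(green[mask]),
                 i_std_red = sd(red[mask]), i_std_green = sd(green[mask]),
                 dapi_sum = sum(dapi[mask]), area = sum(mask))),
    class = "cell_image")
}

# Small field with a few planted nuclei, shared by preprocessing tests.
fx_small_sim <- function(seed = 42, n_nuclei = 3, ...) {
  synth_field(synth_spec(field_size_px = c(360L, 360L), n_nuclei = n_nuclei,
                         rng_seed = seed, ...))
}

# Match analyzed cells back to ground-truth nuclei; returns per-cell truth
# focus counts and per-object focus labels (seed within `tol` px of a
# planted red-visible focus).
fx_label_objects <- function(objects, manifest, truths, crop_half = 60, tol = 3) {
  is_focus <- logical(nrow(objects))
  truth_fpc <- numeric(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    fi <- manifest$cell_id[i] %/% 10000L
    if (fi == 0) fi <- 1
    tr <- truths[[fi]]
    d <- sqrt((tr$nuclei$row - (manifest$origin_row[i] + crop_half))^2 +
              (tr$nuclei$col - (manifest$origin_col[i] + crop_half))^2)
    ni <- tr$nuclei$nucleus[which.min(d)]
    fo <- tr$foci[tr$foci$nucleus == ni & tr$foci$in_red, ]
    truth_fpc[i] <- sum(tr$foci$nucleus == ni)
    for (k in which(objects$cell_id == manifest$cell_id[i])) {
      if (nrow(fo) && any(sqrt((fo$row - (manifest$origin_row[i] + objects$seed_row[k]))^2 +
                               (fo$col - (manifest$origin_col[i] + objects$seed_col[k]))^2) <= tol)) {
        is_focus[k] <- TRUE
      }
    }
  }
  list(is_focus = is_focus, truth_fpc = truth_fpc)
}

# Run segmentation + cropping + gating over a list of simulated fields and
# return analyzed cells with a field-unique id scheme.
fx_process_fields <- function(sims, config = run_config()) {
  all_cells <- list()
  for (fi in seq_along(sims)) {
    field <- sims[[fi]]$field
    labels <- segment_nuclei(field$dapi, min_area = config$seg_min_area,
                             max_area = config$seg_max_area,
                             blur_sigma = config$seg_blur_sigma)
    cells <- crop_cells(field, labels, crop_size = config$crop_size_px)
    for (cl in cells) {
      cl$id <- cl$id + 10000L * fi
      all_cells[[length(all_cells) + 1]] <- cl
    }
  }
  manifest <- filter_g1(cells_manifest(all_cells), k = config$gate_k,
                        min_cells = config$min_gate_cells)
  keep <- manifest$retained %in% TRUE
  list(cells = all_cells[keep], manifest = manifest[keep, ],
       full_manifest = manifest)
}
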