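#' Segment nuclei in a DAPI image
#'
#' Global Otsu threshold on the Gaussian-smoothed DAPI plane, hole filling,
#' optional distance-transform watershed to split touching nuclei, and an
#' area gate. Deterministic for a given image and configuration.
#'
#' @param dapi Numeric matrix of DAPI grey values.
#' @param min_area,max_area Retained nucleus area bounds (px).
#' @param blur_sigma Gaussian smoothing scale before thresholding (px).
#' @param split_touching Split touching nuclei by watershed on the distance
#'   transform.
#' @return An integer label matrix of the same size: 0 is background, labels
#'   `1..k` are nuclei (relabelled consecutively). A blank image yields an
#'   all-zero matrix.
#' @export
segment_nuclei <- function(dapi, min_area = 300, max_area = 10000,
                           blur_sigma = 3, split_touching = TRUE) {
  dapi <- as_image_matrix(dapi, "dapi")
  out <- matrix(0L, nrow(dapi), ncol(dapi))
  if (all(dapi == dapi[1])) return(out)
  img <- EBImage::Image(dapi / 255)
  sm <- EBImage::gblur(img, sigma = blur_sigma)
  th <- EBImage::otsu(sm, range = c(0, 1))
  bw <- sm > th
  bw <- EBImage::fillHull(bw)
  lab <- if (split_touching) {
    EBImage::watershed(EBImage::distmap(bw), tolerance = 1, ext = 1)
  } else {
    EBImage::bwlabel(bw)
  }
  lab <- EBImage::imageData(lab)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area & sizes <= max_area)
  if (length(keep) == 0) return(out)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  pos <- lab > 0
  out[pos] <- remap[lab[pos]]
  out
}

#' Summarise a label matrix
#'
#' @param labels Integer label matrix from [segment_nuclei()].
#' @return Tibble with one row per label: `label`, `area`, centroid
#'   `row`/`col` (unweighted).
#' @export
label_summary <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  purrr::map_dfr(ids, function(id) {
    w <- which(labels == id, arr.ind = TRUE)
    tibble(label = id, area = nrow(w), row = mean(w[, 1]), col = mean(w[, 2]))
  })
}

#' Select the sharpest z-plane of a marker stack
#'
#' Ranks planes by the ratio of total Sobel gradient magnitude to total raw
#' intensity inside the nucleus mask and returns the index of the maximum.
#' The ratio construction makes the choice invariant under multiplication of
#' the whole stack by a positive constant. Planes with zero raw intensity
#' inside the mask are excluded; ties break to the lowest plane index.
#'
#' @param stack Numeric array `(rows, cols, 5)`.
#' @param mask Logical matrix of the nucleus pixels.
#' @return Integer plane index in 1..5, or `NA_integer_` if every plane has
#'   zero in-mask intensity (invalid cell).
#' @export
select_best_plane <- function(stack, mask) {
  stopifnot(length(dim(stack)) == 3, dim(stack)[3] == 5, any(mask))
  ratio <- vapply(1:5, function(p) {
    plane <- stack[, , p]
    tot <- sum(plane[mask])
    if (tot <= 0) return(NA_real_)
    sum(sobel_magnitude(plane)[mask]) / tot
  }, 0)
  if (all(is.na(ratio))) return(NA_integer_)
  which.max(ratio)  # NA-ignoring; first index wins ties
}

#' Crop single-cell images from a field
#'
#' One fixed-size crop per nucleus, centred on the mask centroid (half-open
#' windows, crop pixels are bit-identical to the field window). Cells whose
#' window would cross the field border and cells with no valid focal plane in
#' either marker channel are dropped; drops are reported in the `dropped`
#' attribute with a reason code. Per-cell intensity statistics (mean and sd of
#' each marker's best plane under the mask, integrated DAPI) are computed at
#' crop time.
#'
#' @param field A [field_image()].
#' @param labels Integer label matrix from [segment_nuclei()] (same size).
#' @param crop_size Crop side length in pixels (default 120).
#' @return A list of `cell_image` objects, each with elements `id`, `origin`
#'   (0-based `(row, col)` of the crop's top-left corner), `mask`, `dapi`,
#'   `red_stack`, `green_stack`, `best_red`, `best_green`, `red`, `green`
#'   (best-plane crops) and `stats`. Use [cells_manifest()] for the tabular
#'   view.
#' @export
crop_cells <- function(field, labels, crop_size = 120) {
  stopifnot(inherits(field, "field_image"),
            all(dim(labels) == dim(field$dapi)))
  half <- crop_size %/% 2
  info <- label_summary(labels)
  dropped <- tibble(label = integer(), reason = character())
  cells <- list()
  for (i in seq_len(nrow(info))) {
    id <- info$label[i]
    r0 <- round(info$row[i]) - half
    c0 <- round(info$col[i]) - half
    if (r0 < 0 || c0 < 0 || r0 + crop_size > nrow(labels) ||
        c0 + crop_size > ncol(labels)) {
      dropped <- dplyr::add_row(dropped, label = id, reason = "border_clip")
      next
    }
    rr <- (r0 + 1):(r0 + crop_size); cc <- (c0 + 1):(c0 + crop_size)
    mask <- labels[rr, cc] == id
    w <- which(labels == id, arr.ind = TRUE)
    if (any(w[, 1] <= r0) || any(w[, 1] > r0 + crop_size) ||
        any(w[, 2] <= c0) || any(w[, 2] > c0 + crop_size)) {
      abort("Crop size smaller than a mask bounding box; increase `crop_size`.",
            class = "focimetry_config_error")
    }
    red_stack <- field$red_stack[rr, cc, , drop = FALSE]
    green_stack <- field$green_stack[rr, cc, , drop = FALSE]
    best_red <- select_best_plane(red_stack, mask)
    best_green <- select_best_plane(green_stack, mask)
    if (is.na(best_red) || is.na(best_green)) {
      dropped <- dplyr::add_row(dropped, label = id, reason = "no_valid_plane")
      next
    }
    red <- red_stack[, , best_red]
    green <- green_stack[, , best_green]
    stats <- list(
      i_nucl_red = mean(red[mask]), i_nucl_green = mean(green[mask]),
      i_std_red = sd(red[mask]), i_std_green = sd(green[mask]),
      dapi_sum = sum(field$dapi[rr, cc][mask]), area = sum(mask)
    )
    if (stats$i_nucl_red <= 0 || stats$i_nucl_green <= 0) {
      dropped <- dplyr::add_row(dropped, label = id, reason = "zero_intensity")
      next
    }
    cells[[length(cells) + 1]] <- structure(
      list(id = id, origin = c(row = r0, col = c0), mask = mask,
           dapi = field$dapi[rr, cc],
           red_stack = red_stack, green_stack = green_stack,
           best_red = best_red, best_green = best_green,
           red = red, green = green, stats = stats),
      class = "cell_image")
  }
  attr(cells, "dropped") <- dropped
  cells
}

#' @export
print.cell_image <- function(x, ...) {
  cat("<cell_image> id", x$id, "origin (", x$origin[1], ",", x$origin[2],
      ") area", x$stats$area, "px; best planes red", x$best_red,
      "green", x$best_green, "\n")
  invisible(x)
}

#' Tabular manifest of cropped cells
#'
#' @param cells List of `cell_image` objects from [crop_cells()].
#' @return Tibble with one row per cell: id, crop origin, nucleus area,
#'   best-plane indices, per-channel mean/sd intensities and integrated DAPI.
#' @export
cells_manifest <- function(cells) {
  purrr::map_dfr(cells, function(cl) {
    tibble(cell_id = cl$id, origin_row = cl$origin[["row"]],
           origin_col = cl$origin[["col"]], area = cl$stats$area,
           best_red = cl$best_red, best_green = cl$best_green,
           i_nucl_red = cl$stats$i_nucl_red, i_nucl_green = cl$stats$i_nucl_green,
           i_std_red = cl$stats$i_std_red, i_std_green = cl$stats$i_std_green,
           dapi_sum = cl$stats$dapi_sum)
  })
}

#' Gate the G1 population
#'
#' Rejects S/G2 and dying cells on a two-dimensional gate: integrated DAPI
#' within a robust window around the G1 mode (mode of a kernel-density
#' estimate of log DAPI, +/- `k` robust deviations about that mode) and
#' gamma-H2AX nucleus mean below `median + k * MAD` (removes pan-nuclear
#' signal typical of dying cells). Gate bounds are attached as the `gate`
#' attribute.
#'
#' @param manifest Tibble from [cells_manifest()] (columns `dapi_sum`,
#'   `i_nucl_green`).
#' @param k Gate width in robust deviations (default 2.5).
#' @param min_cells Minimum cells needed to estimate the G1 mode; below this
#'   the gate is refused and `retained` is `NA` for every cell.
#' @return The manifest with logical columns `gate_dapi`, `gate_h2ax`,
#'   `retained` added.
#' @export
filter_g1 <- function(manifest, k = 2.5, min_cells = 10) {
  if (nrow(manifest) == 0) {
    return(dplyr::mutate(manifest, gate_dapi = logical(0),
                         gate_h2ax = logical(0), retained = logical(0)))
  }
  if (nrow(manifest) < min_cells) {
    warn(sprintf("Only %d cells; G1 gating refused (need >= %d). Cells flagged ungated.",
                 nrow(manifest), min_cells))
    return(dplyr::mutate(manifest, gate_dapi = NA, gate_h2ax = NA, retained = NA))
  }
  ld <- log(manifest$dapi_sum)
  dens <- density(ld, n = 512)
  mode_ld <- dens$x[which.max(dens$y)]
  dev <- 1.4826 * median(abs(ld - mode_ld))
  if (dev <= 0) dev <- sd(ld) + .Machine$double.eps
  lo <- mode_ld - k * dev; hi <- mode_ld + k * dev
  g_med <- median(manifest$i_nucl_green)
  g_mad <- mad(manifest$i_nucl_green)
  # a degenerate MAD (many identical values) must not reject typical cells
  g_cap <- g_med + k * max(g_mad, 1e-8)
  out <- dplyr::mutate(manifest,
                       gate_dapi = ld >= lo & ld <= hi,
                       gate_h2ax = .data$i_nucl_green <= g_cap,
                       retained = .data$gate_dapi & .data$gate_h2ax)
  attr(out, "gate") <- list(log_dapi_mode = mode_ld, log_dapi_lo = lo,
                            log_dapi_hi = hi, h2ax_cap = g_cap, k = k)
  out
}
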