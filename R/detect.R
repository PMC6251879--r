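#' Find local intensity maxima
#'
#' A pixel is a local maximum if it lies inside the mask and no other in-mask
#' pixel within Euclidean distance `radius` has a larger value. On plateaus
#' (equal-valued pixels within the radius, common in 8-bit images) only the
#' lexicographically smallest `(row, col)` pixel is kept, which makes the
#' result deterministic.
#'
#' @param image Numeric matrix.
#' @param mask Logical matrix restricting the search; `NULL` for the whole
#'   image.
#' @param radius Neighbourhood radius in pixels (default 3).
#' @return Tibble with columns `row`, `col`, `intensity`, ordered by column
#'   then row.
#' @export
find_local_maxima <- function(image, mask = NULL, radius = 3) {
  image <- as_image_matrix(image)
  if (radius < 1) abort("`radius` must be >= 1.")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  stopifnot(all(dim(mask) == dim(image)))
  m <- cpp_local_maxima(image, mask, radius)
  tibble(row = m[, 1], col = m[, 2], intensity = image[m])
}

#' Grow an object from a seed maximum
#'
#' Area growing: the maximal 8-connected pixel set containing the seed in
#' which every pixel has at least `frac` (default half) of the seed's
#' intensity and at least `min_intensity`. Growth never leaves the mask.
#'
#' @param image Numeric matrix.
#' @param seed Length-2 integer `(row, col)` of a detected maximum.
#' @param mask Logical matrix; `NULL` for the whole image.
#' @param frac Minimum pixel intensity as a fraction of the seed intensity.
#' @param min_intensity Absolute intensity floor applied during growth.
#' @return Tibble with columns `row`, `col`, `intensity`.
#' @export
grow_object <- function(image, seed, mask = NULL, frac = 0.5,
                        min_intensity = -Inf) {
  image <- as_image_matrix(image)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  seeds <- matrix(as.integer(seed), 1, 2)
  px <- cpp_grow_objects(image, mask, seeds, frac, min_intensity)[[1]]
  tibble(row = px[, 1], col = px[, 2], intensity = image[px])
}

#' Detect candidate objects in a single-cell image
#'
#' Runs local-maximum seeding and area growing on the red (53BP1) best plane
#' of a cell. Pixels below `pixel_intensity_factor` times the red nucleus
#' mean are not connectable (the intensity floor is applied during growth,
#' not as an after-the-fact filter), objects smaller than
#' `min_object_area_px` are discarded, and regions grown from multiple seeds
#' stay disjoint (pixels go to the brighter seed, ties to the smaller
#' `(row, col)` seed). The surviving pixel sets are reused verbatim to read
#' features off the green channel at the same coordinates.
#'
#' @param cell A `cell_image` from [crop_cells()].
#' @param config A [run_config()].
#' @return Tibble with one row per object: `cell_id`, `object`, `seed_row`,
#'   `seed_col`, `area`, `mean_red`, `mean_green`, and a `pixels` list-column
#'   of 2-column `(row, col)` matrices.
#' @export
detect_objects <- function(cell, config = run_config()) {
  stopifnot(inherits(cell, "cell_image"))
  img <- cell$red
  floor_val <- config$pixel_intensity_factor * cell$stats$i_nucl_red
  mx <- cpp_local_maxima(img, cell$mask, config$local_max_radius_px)
  if (nrow(mx) > 0) mx <- mx[img[mx] >= floor_val, , drop = FALSE]
  if (nrow(mx) == 0) {
    return(tibble(cell_id = integer(), object = integer(), seed_row = integer(),
                  seed_col = integer(), area = integer(), mean_red = numeric(),
                  mean_green = numeric(), pixels = list()))
  }
  grown <- cpp_grow_objects(img, cell$mask, mx, 0.5, floor_val)
  keep <- vapply(grown, nrow, 0L) >= config$min_object_area_px
  grown <- grown[keep]
  mx <- mx[keep, , drop = FALSE]
  tibble(
    cell_id = rep(cell$id, length(grown)),
    object = seq_along(grown),
    seed_row = mx[, 1], seed_col = mx[, 2],
    area = vapply(grown, nrow, 0L),
    mean_red = vapply(grown, function(p) mean(cell$red[p]), 0),
    mean_green = vapply(grown, function(p) mean(cell$green[p]), 0),
    pixels = grown
  )
}
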