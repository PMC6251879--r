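#' Object compactness
#'
#' Inverse intensity-weighted second moment of an object's pixels about its
#' centre: `C = 1 / sum(r_i^2 * I_i)`, where `r_i` is the distance of pixel
#' `i` to the intensity-weighted centroid — the inverse of a moment of
#' inertia with intensity playing the role of mass. Units: 1 / (grey px^2).
#' For degenerate objects (a single pixel, or all mass at the centroid) the
#' sum is zero and `C` is returned as `NA`; scoring substitutes a cap there
#' (see [score_objects()]).
#'
#' @param pixels 2-column `(row, col)` matrix of the object's pixels.
#' @param intensities Raw intensities of those pixels in the scored channel.
#' @return Compactness `C > 0`, or `NA_real_` when the moment is zero.
#' @export
#' @examples
#' px <- cbind(1, 1:3)
#' compactness(px, c(1, 1, 1))  # centroid at the middle pixel: 1 / 2
compactness <- function(pixels, intensities) {
  pixels <- matrix(as.numeric(pixels), ncol = 2)
  if (nrow(pixels) == 0) abort("Object has no pixels.")
  stopifnot(length(intensities) == nrow(pixels))
  tot <- sum(intensities)
  if (tot <= 0) return(NA_real_)
  cr <- sum(pixels[, 1] * intensities) / tot
  cc <- sum(pixels[, 2] * intensities) / tot
  mom <- sum(((pixels[, 1] - cr)^2 + (pixels[, 2] - cc)^2) * intensities)
  if (mom <= 0) return(NA_real_)
  1 / mom
}

#' Single-channel object score
#'
#' `(I_TH / I_nucl) * I_LC * C`: the top-hat response of the object's three
#' brightest pixels normalized by the nucleus mean, times the
#' local-curvature response of its three brightest pixels, times the object
#' compactness. A negative local-curvature response marks an anti-blob and is
#' clamped to zero, which zeroes the score.
#'
#' @param i_th Mean of the three brightest object pixels in the top-hat
#'   image.
#' @param i_nucl Mean nucleus intensity of the channel (must be positive).
#' @param i_lc Mean of the three brightest object pixels in the
#'   local-curvature image (signed).
#' @param c_comp Object compactness from [compactness()].
#' @return Non-negative score.
#' @export
channel_oep <- function(i_th, i_nucl, i_lc, c_comp) {
  if (any(i_nucl <= 0)) abort("`i_nucl` must be positive.")
  (i_th / i_nucl) * pmax(i_lc, 0) * c_comp
}

#' Per-cell channel weight
#'
#' Ratio of the standard deviations of the in-nucleus pixel intensities of
#' the two marker best planes, `w = sd(red) / sd(green)`, computed for every
#' cell individually. Values above 1 shift weight toward the red (53BP1)
#' channel in [combined_oep()]; typical values lie between 0.9 and 1.2.
#'
#' @param cell A `cell_image`, or a list with `stats$i_std_red` and
#'   `stats$i_std_green`.
#' @return `w > 0`, or `NA_real_` with a warning when the green channel is
#'   constant (degenerate cell, to be excluded).
#' @export
weight_factor <- function(cell) {
  s_red <- cell$stats$i_std_red
  s_green <- cell$stats$i_std_green
  if (is.na(s_green) || s_green <= 0) {
    warn("Constant green channel: cell excluded (degenerate channel).")
    return(NA_real_)
  }
  s_red / s_green
}

#' Combined two-channel object score
#'
#' `OEP = OEP_red^w * OEP_green^(1/w)`: a weighted geometric combination of
#' the per-channel scores in which `w > 1` amplifies the influence of the red
#' channel. At `w = 1` it reduces to the plain product.
#'
#' @param oep_red,oep_green Non-negative per-channel scores.
#' @param w Positive per-cell weight from [weight_factor()].
#' @return Non-negative combined score.
#' @export
#' @examples
#' combined_oep(4, 16, 2)  # 4^2 * 16^(1/2) = 64
combined_oep <- function(oep_red, oep_green, w) {
  if (any(w <= 0)) abort("`w` must be positive.")
  oep_red^w * oep_green^(1 / w)
}

top3_mean <- function(values) {
  mean(sort(values, decreasing = TRUE)[seq_len(min(3, length(values)))])
}

# Default compactness cap for degenerate objects when no >=2 px object is
# available in the same cell to borrow the maximum from.
C_CAP_FALLBACK <- 10

#' Score detected objects
#'
#' Fills the per-object feature record for both channels — top-hat top-3 mean
#' `I_TH`, local-curvature top-3 mean `I_LC`, compactness `C` from the raw
#' best plane — and combines them into the per-channel and combined scores
#' with the cell's channel weight. Degenerate compactness values (single-pixel
#' objects) are capped at the largest `C` observed among multi-pixel objects
#' of the same cell, falling back to a fixed constant.
#'
#' Log representations are attached for histogramming: `log_oep` is the
#' base-10 log with scores at or below zero floored to the smallest positive
#' score of the cell, and `inv_log_oep` is `1 / log10(OEP)` and is `NA` for
#' scores at or below 1 (those objects are excluded from the inverse-log
#' histogram only).
#'
#' @param objects Tibble from [detect_objects()] (needs the `pixels`
#'   list-column).
#' @param cell The `cell_image` the objects came from.
#' @param config A [run_config()].
#' @return The objects tibble (without `pixels`) with columns `i_th_red`,
#'   `i_th_green`, `i_lc_red`, `i_lc_green`, `c_red`, `c_green`, `oep_red`,
#'   `oep_green`, `w`, `oep`, `log_oep`, `inv_log_oep` appended.
#' @export
score_objects <- function(objects, cell, config = run_config()) {
  stopifnot(inherits(cell, "cell_image"))
  w <- weight_factor(cell)
  if (nrow(objects) == 0 || is.na(w)) {
    out <- dplyr::select(objects[0, ], -"pixels")
    return(dplyr::mutate(out, i_th_red = numeric(0), i_th_green = numeric(0),
                         i_lc_red = numeric(0), i_lc_green = numeric(0),
                         c_red = numeric(0), c_green = numeric(0),
                         oep_red = numeric(0), oep_green = numeric(0),
                         w = numeric(0), oep = numeric(0),
                         log_oep = numeric(0), inv_log_oep = numeric(0)))
  }
  th_red <- top_hat(cell$red, config$tophat_diameter_px)
  th_green <- top_hat(cell$green, config$tophat_diameter_px)
  lc_red <- local_curvature(cell$red)
  lc_green <- local_curvature(cell$green)

  feat <- purrr::map_dfr(objects$pixels, function(px) {
    tibble(
      i_th_red = top3_mean(th_red[px]), i_th_green = top3_mean(th_green[px]),
      i_lc_red = top3_mean(lc_red[px]), i_lc_green = top3_mean(lc_green[px]),
      c_red = compactness(px, cell$red[px]),
      c_green = compactness(px, cell$green[px])
    )
  })
  cap_for <- function(cv) {
    finite <- cv[!is.na(cv)]
    if (length(finite) > 0) max(finite) else C_CAP_FALLBACK
  }
  feat$c_red[is.na(feat$c_red)] <- cap_for(feat$c_red)
  feat$c_green[is.na(feat$c_green)] <- cap_for(feat$c_green)

  out <- dplyr::bind_cols(dplyr::select(objects, -"pixels"), feat)
  out <- dplyr::mutate(out,
    oep_red = channel_oep(.data$i_th_red, cell$stats$i_nucl_red,
                          .data$i_lc_red, .data$c_red),
    oep_green = channel_oep(.data$i_th_green, cell$stats$i_nucl_green,
                            .data$i_lc_green, .data$c_green),
    w = w,
    oep = combined_oep(.data$oep_red, .data$oep_green, .data$w))
  add_log_columns(out)
}

# log_oep floors non-positive scores at the smallest positive score in the
# table; inv_log_oep is defined only above 1.
add_log_columns <- function(objects) {
  pos <- objects$oep[objects$oep > 0]
  floor_pos <- if (length(pos) > 0) min(pos) else .Machine$double.xmin
  dplyr::mutate(objects,
    log_oep = log10(pmax(.data$oep, floor_pos)),
    inv_log_oep = ifelse(.data$oep > 1, 1 / log10(.data$oep), NA_real_))
}

#' Detect and score all objects of a set of cells
#'
#' Convenience wrapper chaining [detect_objects()] and [score_objects()] over
#' a list of cells; log columns are recomputed over the pooled table so that
#' the positivity floor is sample-wide.
#'
#' @param cells List of `cell_image` objects.
#' @param config A [run_config()].
#' @return Pooled objects tibble; cells with a degenerate green channel are
#'   skipped.
#' @export
score_cells <- function(cells, config = run_config()) {
  tabs <- purrr::map(cells, function(cl) {
    score_objects(detect_objects(cl, config), cl, config)
  })
  out <- dplyr::bind_rows(tabs)
  if (nrow(out) > 0) out <- add_log_columns(out)
  out
}
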