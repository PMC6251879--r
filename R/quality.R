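#' Per-cell channel correlation
#'
#' Pearson correlation between the red and green best-plane pixel
#' intensities under the nucleus mask. Genuine foci appear in both damage
#' markers, so well-stained samples correlate strongly; a constant channel
#' makes the correlation undefined and the cell is skipped.
#'
#' @param cell A `cell_image`.
#' @return Correlation in [-1, 1], or `NA_real_` for a constant channel.
#' @export
channel_pearson <- function(cell) {
  stopifnot(inherits(cell, "cell_image"), sum(cell$mask) >= 2)
  r <- cell$red[cell$mask]; g <- cell$green[cell$mask]
  if (sd(r) == 0 || sd(g) == 0) return(NA_real_)
  cor(r, g)
}

#' Sample-level channel correlation
#'
#' @param cells List of `cell_image` objects.
#' @return List with `mean_pearson` and a `per_cell` tibble (`cell_id`,
#'   `pearson`); constant-channel cells are excluded from the mean with a
#'   logged reason column.
#' @export
sample_pearson <- function(cells) {
  per_cell <- purrr::map_dfr(cells, function(cl) {
    p <- channel_pearson(cl)
    tibble(cell_id = cl$id, pearson = p,
           skipped = is.na(p),
           reason = if (is.na(p)) "constant_channel" else NA_character_)
  })
  list(mean_pearson = mean(per_cell$pearson, na.rm = TRUE), per_cell = per_cell)
}

#' Histogram bimodality check
#'
#' A histogram counts as bimodal when its smoothed counts show at least two
#' modes whose interposed valley is at least `prominence` (fraction) below
#' the smaller of the two tallest modes.
#'
#' @param hist An [oep_histogram()].
#' @param prominence Required relative valley depth (default 0.1).
#' @return List with `bimodal`, the two `mode_mids` (or fewer) and
#'   `valley_mid` / `valley_depth_frac` when found.
#' @export
histogram_bimodality <- function(hist, prominence = 0.1) {
  v <- find_valley(hist$mid, hist$smoothed, min_height_abs = 3)
  if (is.null(v)) {
    return(list(bimodal = FALSE, mode_mids = numeric(0), valley_mid = NA_real_,
                valley_depth_frac = NA_real_))
  }
  list(bimodal = v$prominence >= prominence,
       mode_mids = c(v$left_mode, v$right_mode),
       valley_mid = v$valley, valley_depth_frac = v$prominence)
}

#' Sample quality gate
#'
#' A sample passes when the mean channel correlation exceeds `pearson_min`
#' (default 0.4, an empirical bound for specific double staining) and the
#' log-score histogram shows a pronounced bimodal minimum. Samples failing
#' either check should be discarded; the reasons are enumerated.
#'
#' @param mean_pearson Mean per-nucleus channel correlation.
#' @param hist An [oep_histogram()] of the sample's combined scores.
#' @param pearson_min Minimum acceptable mean correlation.
#' @param prominence Required relative valley depth for bimodality.
#' @return Object of class `quality_check`: list with `pass`, `reasons`
#'   (character, empty when passing), `mean_pearson` and the bimodality
#'   detail.
#' @export
sample_quality <- function(mean_pearson, hist, pearson_min = 0.4,
                           prominence = 0.1) {
  bim <- histogram_bimodality(hist, prominence)
  reasons <- character(0)
  if (!is.finite(mean_pearson) || mean_pearson <= pearson_min) {
    reasons <- c(reasons, "low_pearson")
  }
  if (!bim$bimodal) reasons <- c(reasons, "no_histogram_minimum")
  structure(list(pass = length(reasons) == 0, reasons = reasons,
                 mean_pearson = mean_pearson, pearson_min = pearson_min,
                 bimodality = bim),
            class = "quality_check")
}

#' @export
print.quality_check <- function(x, ...) {
  cat("<quality_check>", if (x$pass) "PASS" else
    paste("FAIL:", paste(x$reasons, collapse = ", ")),
    "| mean Pearson", format(x$mean_pearson, digits = 3), "\n")
  invisible(x)
}

#' @method glance quality_check
#' @export
glance.quality_check <- function(x, ...) {
  tibble(pass = x$pass, reasons = paste(x$reasons, collapse = ";"),
         mean_pearson = x$mean_pearson, bimodal = x$bimodality$bimodal,
         valley_depth_frac = x$bimodality$valley_depth_frac)
}

#' Benchmark candidate scorers against manual ratings
#'
#' Spearman rank correlation between each candidate object scorer and the
#' mean manual rating, plus the inter-rater correlation matrix. To compare
#' binary classifications, each scorer's threshold is aligned so that it
#' calls the same number of foci as the raters do (ratings of 5 and above),
#' and the resulting disagreement count is reported.
#'
#' @param objects Scored objects tibble (columns `cell_id`, `object` and the
#'   scorer columns below).
#' @param ratings Tibble with columns `cell_id`, `object`, `rater`, `rating`
#'   (1-9 scale; 5 and above means focus). At least 3 rated objects.
#' @param scorers Named character vector mapping scorer labels to object
#'   columns; defaults to the derivation chain from raw means through the
#'   combined score.
#' @return List with `scorer_rho` (tibble: scorer, rho, n, mismatches),
#'   `rater_rho` (matrix) and `rated` (the merged table).
#' @export
benchmark_scorers <- function(objects, ratings,
                              scorers = c(raw_mean_red = "mean_red",
                                          raw_mean_green = "mean_green",
                                          tophat_top3_red = "i_th_red",
                                          tophat_top3_green = "i_th_green",
                                          lc_top3_red = "i_lc_red",
                                          lc_top3_green = "i_lc_green",
                                          oep_red = "oep_red",
                                          oep_green = "oep_green",
                                          oep_combined = "oep")) {
  mean_rating <- ratings |>
    dplyr::group_by(.data$cell_id, .data$object) |>
    dplyr::summarise(rating = mean(.data$rating), .groups = "drop")
  if (nrow(mean_rating) < 3) abort("Fewer than 3 rated objects: refused.")
  merged <- dplyr::inner_join(mean_rating, objects, by = c("cell_id", "object"))
  n_foci_manual <- sum(merged$rating >= 5)
  scorer_rho <- purrr::imap_dfr(scorers, function(col, label) {
    s <- merged[[col]]
    rho <- suppressWarnings(cor(s, merged$rating, method = "spearman"))
    # equal-foci-count alignment: scorer calls as many foci as the raters
    called <- rank(-s, ties.method = "first") <= n_foci_manual
    tibble(scorer = label, rho = rho, n = nrow(merged),
           mismatches = sum(called != (merged$rating >= 5)))
  })
  wide <- ratings |>
    tidyr::pivot_wider(id_cols = c("cell_id", "object"),
                       names_from = "rater", values_from = "rating")
  rater_cols <- setdiff(names(wide), c("cell_id", "object"))
  rater_rho <- if (length(rater_cols) < 2) {
    matrix(1, 1, 1, dimnames = list(rater_cols, rater_cols))
  } else {
    suppressWarnings(cor(as.matrix(wide[rater_cols]), method = "spearman",
                         use = "pairwise.complete.obs"))
  }
  list(scorer_rho = scorer_rho, rater_rho = rater_rho, rated = merged)
}

#' Synthetic manual-rating oracle
#'
#' Emulates experimenters rating objects on the 1-9 scale, where background
#' signals occupy 1-4 and foci 5-9: an object classified as a focus (seen in
#' both marker channels) is rated by an affine map of its log planted
#' amplitude onto the focus band, a background signal onto the background
#' band, each plus independent per-rater Gaussian noise, rounded to 0.5
#' steps and clamped to [1, 9]. Objects not matched to any planted blob
#' rate at the bottom of the scale.
#'
#' @param amplitudes Planted blob amplitude per object (`NA` for unmatched
#'   objects).
#' @param is_focus Logical: object matched to a planted co-localized focus
#'   (rated in the 5-9 band) rather than a background signal (1-4 band).
#' @param n_raters Number of simulated raters.
#' @param noise_sd Rating noise sd (rating units).
#' @param seed Integer seed.
#' @return Tibble with `idx` (position in `amplitudes`), `rater`, `rating`.
#' @export
synthetic_ratings <- function(amplitudes, is_focus, n_raters = 3,
                              noise_sd = 0.7, seed = 1L) {
  stopifnot(length(is_focus) == length(amplitudes))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  la <- log(amplitudes)
  band <- function(x, lo, hi) {
    rng <- range(x, na.rm = TRUE)
    lo + (hi - lo) * (x - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  }
  base <- numeric(length(la))
  base[is_focus] <- band(la[is_focus], 5.5, 8.5)
  base[!is_focus] <- band(la[!is_focus], 1.5, 3.5)
  base[is.na(base) | is.na(la)] <- 1
  purrr::map_dfr(seq_len(n_raters), function(r) {
    raw <- base + rnorm(length(base), 0, noise_sd)
    tibble(idx = seq_along(base), rater = paste0("rater", r),
           rating = pmin(pmax(round(raw * 2) / 2, 1), 9))
  })
}
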