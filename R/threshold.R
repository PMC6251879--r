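#' Histogram of object scores
#'
#' Bins the log10 scores (`mode = "log"`) or their reciprocals
#' (`mode = "inverse_log"`, defined only for scores above 1) and attaches a
#' moving-average smoothed count used for mode finding.
#'
#' @param oeps Numeric vector of combined scores (positive values are used).
#' @param mode `"log"` or `"inverse_log"`.
#' @param bins Number of equal-width bins.
#' @param smooth Odd moving-average window (bins) for the smoothed counts.
#' @return Object of class `oep_histogram`: a tibble with `mid`, `count`,
#'   `smoothed`, plus attributes `edges`, `mode` and `n_included`.
#' @export
oep_histogram <- function(oeps, mode = c("log", "inverse_log"), bins = 60,
                          smooth = 5) {
  mode <- match.arg(mode)
  x <- oeps[is.finite(oeps) & oeps > 0]
  if (mode == "inverse_log") x <- x[x > 1]
  if (length(x) == 0) {
    abort("No usable positive scores: empty histogram.",
          class = "focimetry_empty_histogram")
  }
  v <- if (mode == "log") log10(x) else 1 / log10(x)
  edges <- seq(min(v), max(v), length.out = bins + 1)
  if (edges[1] == edges[bins + 1]) {
    edges <- seq(edges[1] - 0.5, edges[1] + 0.5, length.out = bins + 1)
  }
  idx <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = bins)
  out <- tibble(mid = (edges[-1] + edges[-(bins + 1)]) / 2,
                count = counts,
                smoothed = smooth_counts(counts, smooth))
  structure(out, edges = edges, mode = mode, n_included = length(v),
            class = c("oep_histogram", class(out)))
}

smooth_counts <- function(counts, window) {
  if (window <= 1) return(as.numeric(counts))
  h <- window %/% 2
  n <- length(counts)
  vapply(seq_len(n), function(i) {
    mean(counts[max(1, i - h):min(n, i + h)])
  }, 0)
}

# Local maxima / minima of a smoothed count vector by exhaustive scan.
# A mode is a bin strictly greater than its neighbours (plateaus collapse to
# their first bin).
scan_modes <- function(smoothed) {
  n <- length(smoothed)
  modes <- integer(0)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && smoothed[j + 1] == smoothed[i]) j <- j + 1
    left_ok <- i == 1 || smoothed[i - 1] < smoothed[i]
    right_ok <- j == n || smoothed[j + 1] < smoothed[i]
    if (left_ok && right_ok && smoothed[i] > 0) modes <- c(modes, i)
    i <- j + 1
  }
  modes
}

#' Modes of a score histogram
#'
#' @param hist An [oep_histogram()].
#' @return Tibble of mode bins (`bin`, `mid`, `height`), tallest first.
#' @export
histogram_modes <- function(hist) {
  idx <- scan_modes(hist$smoothed)
  out <- tibble(bin = idx, mid = hist$mid[idx], height = hist$smoothed[idx])
  dplyr::arrange(out, dplyr::desc(.data$height))
}

# Valley bounding the high-score mode from the left. The focus population
# occupies the rightmost mode of the (smoothed) score curve, so the
# detection valley is the most pronounced minimum between any earlier mode
# and the last mode above the height floor; background sub-structure
# (several low-score classes) must not capture it. Returns NULL when no
# such valley has positive prominence.
find_valley <- function(xs, ys, min_height_frac = 0.02, min_height_abs = 0) {
  peaks <- scan_modes(ys)
  floor_h <- max(min_height_abs, min_height_frac * max(ys[peaks], 0))
  peaks <- peaks[ys[peaks] >= floor_h]
  if (length(peaks) < 2) return(NULL)
  b <- peaks[length(peaks)]
  best <- NULL
  for (a in peaks[-length(peaks)]) {
    v <- a + which.min(ys[a:b]) - 1
    smaller <- min(ys[a], ys[b])
    prom <- (smaller - ys[v]) / smaller
    if (prom <= 0) next
    if (is.null(best) || prom > best$prominence ||
        (prom == best$prominence && smaller > best$smaller)) {
      best <- list(left_mode = xs[a], right_mode = xs[b], valley = xs[v],
                   prominence = prom, smaller = smaller)
    }
  }
  best
}

# --- starting-threshold estimators (each works on log10 scores) -----------

est_kde_valley <- function(logs) {
  dens <- density(logs, n = 512)
  v <- find_valley(dens$x, dens$y)
  if (is.null(v)) return(NA_real_)
  v$valley
}

# Two-component univariate Gaussian EM initialized from a hard split.
# Initializing at the histogram valley keeps the minority focus component
# from being swallowed when the mixture is strongly unbalanced.
fit_gmm2 <- function(x, init_split, max_iter = 300, tol = 1e-10) {
  z <- as.numeric(x >= init_split)
  if (sum(z) < 2 || sum(1 - z) < 2) return(NULL)
  pr <- c(mean(1 - z), mean(z))
  mu <- c(mean(x[z == 0]), mean(x[z == 1]))
  s2 <- c(stats::var(x[z == 0]), stats::var(x[z == 1]))
  s2 <- pmax(s2, 1e-8)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- pr[1] * stats::dnorm(x, mu[1], sqrt(s2[1]))
    d2 <- pr[2] * stats::dnorm(x, mu[2], sqrt(s2[2]))
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d2 / tot
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
    n2 <- sum(g); n1 <- length(x) - n2
    if (n1 < 1 || n2 < 1) return(NULL)
    pr <- c(n1, n2) / length(x)
    mu <- c(sum((1 - g) * x) / n1, sum(g * x) / n2)
    s2 <- pmax(c(sum((1 - g) * (x - mu[1])^2) / n1,
                 sum(g * (x - mu[2])^2) / n2), 1e-8)
  }
  list(pr = pr, mu = mu, s2 = s2)
}

# Density-equality point of two weighted Gaussians, restricted to the
# interval between the means.
gaussian_intersection <- function(pr, mu, s2) {
  ord <- order(mu)
  mu <- mu[ord]; s2 <- s2[ord]; pr <- pr[ord]
  if (diff(mu) < 1e-6) return(NA_real_)
  a <- 1 / s2[1] - 1 / s2[2]
  b <- -2 * (mu[1] / s2[1] - mu[2] / s2[2])
  cc <- mu[1]^2 / s2[1] - mu[2]^2 / s2[2] +
    log(s2[1] / s2[2]) - 2 * log(pr[1] / pr[2])
  roots <- if (abs(a) < 1e-12) -cc / b else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) return(NA_real_)
    (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  inside <- roots[roots > mu[1] & roots < mu[2]]
  if (length(inside) == 0) return(NA_real_)
  inside[1]
}

est_gmm_intersection <- function(logs) {
  v <- log_hist_valley(logs)
  if (is.null(v)) return(NA_real_)
  fit <- fit_gmm2(logs, v$valley)
  if (is.null(fit)) return(NA_real_)
  gaussian_intersection(fit$pr, fit$mu, fit$s2)
}

# smoothed 60-bin histogram of a log-score sample, and its best valley
log_hist_smoothed <- function(logs) {
  e60 <- seq(min(logs), max(logs), length.out = 61)
  sm <- smooth_counts(tabulate(findInterval(logs, e60, rightmost.closed = TRUE,
                                            all.inside = TRUE), nbins = 60), 5)
  list(mid = (e60[-1] + e60[-61]) / 2, smoothed = sm)
}

log_hist_valley <- function(logs) {
  sm <- log_hist_smoothed(logs)
  find_valley(sm$mid, sm$smoothed, min_height_abs = 3)
}

est_otsu <- function(logs, bins = 256) {
  if (length(unique(logs)) < 2) return(NA_real_)
  edges <- seq(min(logs), max(logs), length.out = bins + 1)
  counts <- tabulate(findInterval(logs, edges, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = bins)
  mids <- (edges[-1] + edges[-(bins + 1)]) / 2
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[bins]
  denom <- omega * (1 - omega)
  between <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, -Inf)
  best <- which.max(between[-bins])
  th <- edges[best + 1]
  # validity: the threshold must lie in the bottom of the smoothed
  # histogram's most pronounced dip (below the valley height plus a quarter
  # of its depth); otherwise Otsu split a mode, not background from foci
  v <- log_hist_valley(logs)
  if (is.null(v) || th <= v$left_mode || th >= v$right_mode) return(NA_real_)
  sm <- log_hist_smoothed(logs)
  h_at <- stats::approx(sm$mid, sm$smoothed, th, rule = 2)$y
  h_valley <- stats::approx(sm$mid, sm$smoothed, v$valley, rule = 2)$y
  if (h_at > h_valley + 0.25 * (v$smaller - h_valley)) return(NA_real_)
  th
}

#' Estimate the starting threshold at the bimodal valley
#'
#' Runs three independent estimators of the transition point on the log10
#' scores — the kernel-density valley between the two tallest modes, the
#' intersection of a two-component Gaussian mixture fit, and Otsu's
#' between-class threshold — and returns their mean. An estimator that fails
#' to find a valley is dropped (and logged in the `estimates` element).
#'
#' @param oeps Positive combined scores.
#' @return Object of class `start_threshold`: list with `log_threshold`
#'   (mean of the surviving estimators, log10 scale), `threshold` (linear
#'   scale) and an `estimates` tibble (`method`, `value`, `used`).
#' @export
estimate_start_threshold <- function(oeps) {
  x <- oeps[is.finite(oeps) & oeps > 0]
  if (length(x) < 10) abort("Too few positive scores to estimate a threshold.")
  logs <- log10(x)
  est <- tibble(
    method = c("kde_valley", "gmm_intersection", "otsu"),
    value = c(est_kde_valley(logs), est_gmm_intersection(logs), est_otsu(logs)))
  est$used <- !is.na(est$value)
  if (!any(est$used)) {
    abort("All starting-threshold estimators failed: no valley found.",
          class = "focimetry_no_threshold")
  }
  lt <- mean(est$value[est$used])
  structure(list(log_threshold = lt, threshold = 10^lt, estimates = est),
            class = "start_threshold")
}

#' @export
print.start_threshold <- function(x, ...) {
  cat("<start_threshold> log10 =", format(x$log_threshold, digits = 4),
      "(", sum(x$estimates$used), "of", nrow(x$estimates), "estimators )\n")
  invisible(x)
}

#' Foci per cell at a threshold
#'
#' Objects with a combined score at or above the threshold count as foci;
#' the total is divided by the number of analyzed cells (including cells
#' without any detected object).
#'
#' @param objects Tibble with an `oep` column.
#' @param threshold Linear-scale score threshold.
#' @param n_cells Number of analyzed (gated) cells; must be positive.
#' @return Foci per cell (non-increasing in `threshold`).
#' @export
count_foci <- function(objects, threshold, n_cells) {
  if (n_cells <= 0) abort("`n_cells` must be positive.")
  sum(objects$oep >= threshold) / n_cells
}

#' Rater oracle from a label table
#'
#' Builds the rating callback used by [adjust_threshold()] from a table of
#' per-object binary labels. The returned function receives the displayed
#' batch (rows of the objects table) and answers `TRUE` for focus.
#'
#' @param labels Tibble with columns `cell_id`, `object` and logical
#'   `is_focus`.
#' @return A function `batch -> logical`.
#' @export
oracle_from_labels <- function(labels) {
  key <- paste(labels$cell_id, labels$object, sep = "#")
  verdicts <- setNames(labels$is_focus, key)
  function(batch) {
    v <- verdicts[paste(batch$cell_id, batch$object, sep = "#")]
    v[is.na(v)] <- FALSE
    unname(v)
  }
}

#' Ideal rater with a fixed decision boundary
#'
#' @param t_star Linear-scale score boundary: objects scoring at or above it
#'   are rated focus.
#' @return A function `batch -> logical` for [adjust_threshold()].
#' @export
oracle_threshold <- function(t_star) {
  function(batch) batch$oep >= t_star
}

#' Iterative rater-in-the-loop threshold adjustment
#'
#' Starting from the automated estimate, repeatedly presents the four objects
#' whose scores are closest to the current threshold to a rater and shifts
#' the threshold on the log scale by `-step * (fraction rated focus - 1/2) * 2`:
#' objects rated foci push the threshold down to admit them, objects rated
#' background push it up. The step shrinks geometrically each iteration
#' (floored at one histogram bin width), so early moves are large and later
#' ones fine. After each move the foci-per-cell value is recorded; the loop
#' stops when the standard deviation of the last six foci-per-cell values
#' drops below 5% of their mean, and the final estimate is the mean over the
#' last six thresholds.
#'
#' @param objects Scored objects tibble (needs `oep`, `log_oep`, `cell_id`,
#'   `object`).
#' @param n_cells Number of analyzed cells.
#' @param oracle Rating callback (`batch -> logical`), e.g.
#'   [oracle_from_labels()] or an interactive prompt.
#' @param start A [estimate_start_threshold()] result, or a numeric log10
#'   threshold.
#' @param batch_size Objects displayed per iteration (default 4).
#' @param step Initial log10 step; default is a quarter of the distance
#'   between the two tallest histogram modes (0.25 if the histogram is not
#'   bimodal).
#' @param decay Geometric step decay per iteration.
#' @param sd_frac Stop rule: sd(last six foci-per-cell) below this fraction
#'   of their mean.
#' @param max_iter Iteration cap; reaching it returns a non-converged
#'   session.
#' @param bins Bins of the log histogram used for the default step and the
#'   step floor.
#' @return Object of class `foci_session`; see [tidy.foci_session()] and
#'   [glance.foci_session()].
#' @export
adjust_threshold <- function(objects, n_cells, oracle, start = NULL,
                             batch_size = 4, step = NULL, decay = 0.8,
                             sd_frac = 0.05, max_iter = 60, bins = 60) {
  stopifnot(nrow(objects) >= batch_size)
  if (is.null(start)) start <- estimate_start_threshold(objects$oep)
  t_log <- if (inherits(start, "start_threshold")) start$log_threshold else start
  hist <- oep_histogram(objects$oep, "log", bins = bins)
  bin_w <- diff(attr(hist, "edges"))[1]
  if (is.null(step)) {
    v <- find_valley(hist$mid, hist$smoothed, min_height_abs = 3)
    step <- if (!is.null(v)) (v$right_mode - v$left_mode) / 4 else 0.25
  }
  step <- max(step, bin_w)

  thresholds <- numeric(0); fpc <- numeric(0); frac_focus <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d <- abs(objects$log_oep - t_log)
    batch <- objects[order(d)[seq_len(batch_size)], , drop = FALSE]
    verdict <- as.logical(oracle(batch))
    stopifnot(length(verdict) == batch_size)
    fr <- mean(verdict)
    t_log <- t_log - step * (fr - 0.5) * 2
    step <- max(step * decay, bin_w)
    thresholds <- c(thresholds, t_log)
    fpc <- c(fpc, count_foci(objects, 10^t_log, n_cells))
    frac_focus <- c(frac_focus, fr)
    if (length(fpc) >= 6) {
      last6 <- tail(fpc, 6)
      if (mean(last6) > 0 && sd(last6) < sd_frac * mean(last6)) {
        converged <- TRUE
        break
      }
    }
  }
  final_fpc <- if (length(fpc) >= 6) mean(tail(fpc, 6)) else mean(fpc)
  final_log <- if (length(thresholds) >= 6) mean(tail(thresholds, 6)) else mean(thresholds)
  structure(list(
    start_log_threshold = if (inherits(start, "start_threshold")) start$log_threshold else start,
    thresholds = thresholds, foci_per_cell = fpc, frac_focus = frac_focus,
    converged = converged, iterations = length(thresholds),
    final_log_threshold = final_log, final_foci_per_cell = final_fpc,
    n_cells = n_cells, sd_frac = sd_frac
  ), class = "foci_session")
}

#' @export
print.foci_session <- function(x, ...) {
  cat("<foci_session>", x$iterations, "iterations;",
      if (x$converged) "converged;" else "NOT converged;",
      "foci/cell =", format(x$final_foci_per_cell, digits = 4),
      "at log10 threshold", format(x$final_log_threshold, digits = 4), "\n")
  invisible(x)
}

#' Tidy a threshold-adjustment session
#'
#' @param x A `foci_session`.
#' @param ... Unused.
#' @return Tibble with one row per iteration: `iteration`, `log_threshold`,
#'   `foci_per_cell`, `frac_focus`.
#' @method tidy foci_session
#' @export
tidy.foci_session <- function(x, ...) {
  tibble(iteration = seq_along(x$thresholds), log_threshold = x$thresholds,
         foci_per_cell = x$foci_per_cell, frac_focus = x$frac_focus)
}

#' One-row summary of a threshold-adjustment session
#'
#' @param x A `foci_session`.
#' @param ... Unused.
#' @return Tibble with `iterations`, `converged`, `final_log_threshold`,
#'   `final_foci_per_cell`, `cv_last6` (sd / mean of the trailing six
#'   foci-per-cell values).
#' @method glance foci_session
#' @export
glance.foci_session <- function(x, ...) {
  last6 <- tail(x$foci_per_cell, 6)
  tibble(iterations = x$iterations, converged = x$converged,
         final_log_threshold = x$final_log_threshold,
         final_foci_per_cell = x$final_foci_per_cell,
         cv_last6 = if (length(last6) >= 2 && mean(last6) > 0)
           sd(last6) / mean(last6) else NA_real_)
}
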