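#' Plot a score histogram
#'
#' Bars of the binned counts with the smoothed curve used for mode finding;
#' an optional vertical line marks a threshold (on the histogram's scale).
#'
#' @param object An [oep_histogram()].
#' @param threshold Optional threshold to mark (log10 scale for a log
#'   histogram).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot oep_histogram
#' @export
autoplot.oep_histogram <- function(object, threshold = NULL, ...) {
  lab <- if (attr(object, "mode") == "log") "log10 OEP" else "1 / log10 OEP"
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = diff(attr(object, "edges"))[1],
                      fill = "grey70", colour = "grey40", linewidth = 0.1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), colour = "firebrick") +
    ggplot2::labs(x = lab, y = "objects") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = "dashed")
  }
  p
}

#' Plot a threshold-adjustment session
#'
#' Threshold and foci-per-cell trajectories over the iterations of the
#' rater-in-the-loop adjustment.
#'
#' @param object A `foci_session`.
#' @param ... Unused.
#' @return A ggplot object (two facets).
#' @method autoplot foci_session
#' @export
autoplot.foci_session <- function(object, ...) {
  hist_tbl <- tidy(object) |>
    tidyr::pivot_longer(c("log_threshold", "foci_per_cell"),
                        names_to = "series", values_to = "value")
  ggplot2::ggplot(hist_tbl,
                  ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot repair efficiency against dose
#'
#' @param results Tibble from [repair_efficiency()] (possibly row-bound over
#'   doses).
#' @return A ggplot object with a log dose axis.
#' @export
plot_repair_efficiency <- function(results) {
  ggplot2::ggplot(results, ggplot2::aes(x = .data$dose_gy * 1000,
                                        y = .data$persisting_fraction)) +
    ggplot2::geom_col(fill = "grey60") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (mGy)", y = "persisting foci (%)") +
    ggplot2::theme_minimal()
}
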