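#' Expected radiation-induced foci under the linear induction model
#'
#' Focus induction is linear in dose with a calibration of 20 foci per cell
#' per gray: `induced = rate * dose`.
#'
#' @param dose_gy Dose in gray (non-negative).
#' @param rate Induction rate in foci per cell per gray (default 20).
#' @return Expected induced foci per cell.
#' @export
#' @examples
#' induced_foci(0.012)  # 0.24 foci per cell at 12 mGy
#' induced_foci(1)      # 20 foci per cell at 1 Gy
induced_foci <- function(dose_gy, rate = 20) {
  if (any(dose_gy < 0)) abort("`dose_gy` must be non-negative.")
  rate * dose_gy
}

#' Dose equivalent of a foci level
#'
#' Inverts the linear induction model numerically: the dose (in gray) at
#' which [induced_foci()] predicts the given foci-per-cell level. Useful to
#' express a spontaneous foci level as an equivalent dose.
#'
#' @param foci_per_cell Target foci level (non-negative).
#' @param rate Induction rate in foci per cell per gray.
#' @return Dose in gray.
#' @export
#' @examples
#' dose_equivalent(0.3) * 1000  # 15 mGy
dose_equivalent <- function(foci_per_cell, rate = 20) {
  if (any(foci_per_cell < 0)) abort("`foci_per_cell` must be non-negative.")
  vapply(foci_per_cell, function(f) {
    if (f == 0) return(0)
    upper <- max(1, 2 * f / rate)
    uniroot(function(d) induced_foci(d, rate) - f, c(0, upper),
            tol = 1e-12)$root
  }, 0)
}

#' Repair efficiency as the persisting-focus fraction
#'
#' The radiation-induced persisting foci (irradiated minus control
#' foci-per-cell, at some time after exposure) divided by the foci initially
#' induced by the dose under the linear induction model, in percent. A
#' non-positive difference (irradiated at or below control) is reported as
#' is, with a flag.
#'
#' @param irradiated_fpc,control_fpc Foci per cell in the irradiated and
#'   control samples.
#' @param dose_gy Dose in gray (positive).
#' @param rate Induction rate in foci per cell per gray.
#' @return Tibble with `dose_gy`, `induced`, `persisting` (difference),
#'   `persisting_fraction` (percent) and `nonpositive` flag.
#' @export
#' @examples
#' repair_efficiency(1.30, 0.30, 1)$persisting_fraction  # 5 percent
repair_efficiency <- function(irradiated_fpc, control_fpc, dose_gy, rate = 20) {
  if (any(dose_gy <= 0)) abort("`dose_gy` must be positive.")
  induced <- induced_foci(dose_gy, rate)
  persisting <- irradiated_fpc - control_fpc
  tibble(dose_gy = dose_gy, induced = induced, persisting = persisting,
         persisting_fraction = 100 * persisting / induced,
         nonpositive = persisting <= 0)
}
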