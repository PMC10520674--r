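#' Default sweep grids over the physiological ranges
#'
#' Per-side gaps spanning 10--150 um (linear) and interstitial viscosities
#' spanning 1.2--100 mPa s (log-spaced), the ranges over which the
#' micromotion-driven shear is mapped.
#'
#' @param n number of grid values (>= 8).
#' @return numeric vector in SI units (m, Pa s), sorted ascending.
#' @export
default_sweep_gaps <- function(n = 8L) {
  if (n < 8L) abort_invalid("`n` must be >= 8.")
  um_to_m(seq(10, 150, length.out = n))
}

#' @rdname default_sweep_gaps
#' @export
default_sweep_viscosities <- function(n = 8L) {
  if (n < 8L) abort_invalid("`n` must be >= 8.")
  mpas_to_pas(exp(seq(log(1.2), log(100), length.out = n)))
}

#' Gap-by-viscosity sweep of micromotion-induced wall shear stress
#'
#' Evaluates the quasi-steady gap-flow model over every combination of
#' per-side gap and fluid viscosity, returning a long-form (tidy) table
#' with both shear metrics per cell. Along each viscosity the shear falls
#' strictly with gap; along each gap it rises strictly with viscosity.
#'
#' @param gaps per-side gaps (m), sorted ascending.
#' @param viscosities dynamic viscosities (Pa s), sorted ascending.
#' @param waveform a [micromotion_waveform()].
#' @param density fluid density (kg/m^3), default 1006 (interstitial).
#' @param end_condition cavity ends, `"closed"` (default) or `"open"`.
#' @return A `sweep_result` tibble with one row per cell: `gap` (m),
#'   `viscosity` (Pa s), `wss_peak`, `wss_cycle_avg` (Pa, tissue-wall
#'   magnitudes) and `womersley`. Provenance (package version, waveform)
#'   is attached as attributes.
#' @examples
#' sw <- run_sweep()
#' dplyr::filter(sw, abs(gap - 50e-6) < 1e-9)
#' @export
run_sweep <- function(gaps = default_sweep_gaps(),
                      viscosities = default_sweep_viscosities(),
                      waveform = micromotion_waveform(),
                      density = 1006,
                      end_condition = c("closed", "open")) {
  check_finite(gaps, "gaps")
  check_finite(viscosities, "viscosities")
  if (any(gaps <= 0) || any(viscosities <= 0)) {
    abort_invalid("`gaps` and `viscosities` must be positive.")
  }
  if (is.unsorted(gaps, strictly = TRUE) ||
      is.unsorted(viscosities, strictly = TRUE)) {
    abort_invalid("`gaps` and `viscosities` must be strictly ascending.")
  }
  check_waveform(waveform)
  check_positive_scalar(density, "density")
  end_condition <- match.arg(end_condition)

  s_peak <- metric_speed(waveform, "peak")
  s_avg <- metric_speed(waveform, "cycle_avg")
  k_end <- if (end_condition == "closed") 2 else 1
  f_max <- max(waveform$components$frequency)

  out <- tidyr::expand_grid(gap = gaps, viscosity = viscosities)
  out <- dplyr::mutate(
    out,
    wss_peak = k_end * .data$viscosity * s_peak / .data$gap,
    wss_cycle_avg = k_end * .data$viscosity * s_avg / .data$gap,
    womersley = .data$gap *
      sqrt(2 * pi * f_max * density / .data$viscosity)
  )
  if (!all(is.finite(as.matrix(out)))) {
    bad <- out[!is.finite(out$wss_peak) | !is.finite(out$wss_cycle_avg), ]
    abort(sprintf("sweep produced non-finite values at gap = %g, mu = %g.",
                  bad$gap[1], bad$viscosity[1]),
          class = "perimotion_solver_failure")
  }
  attr(out, "package_version") <- as.character(utils::packageVersion("perimotion"))
  attr(out, "waveform") <- waveform
  attr(out, "end_condition") <- end_condition
  class(out) <- c("sweep_result", class(out))
  out
}
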