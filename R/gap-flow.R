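#' Quasi-steady wall shear stress in the peri-electrode gap
#'
#' Plane-Couette shear across the fluid gap between a moving electrode wall
#' (speed `U`) and the stationary tissue wall, in the quasi-steady regime
#' (Womersley number `alpha << 1`). For a sealed cavity ("closed" ends) the
#' end walls force the net cross-gap flux to zero, adding a pressure-driven
#' backflow to the linear Couette profile; the resulting wall gradients give
#' \deqn{|\tau_{tissue}| = 2\mu U / h, \qquad |\tau_{electrode}| = 4\mu U / h.}
#' For open ends both walls see the plain Couette value \eqn{\mu U / h}.
#'
#' The reported stress is \eqn{\mu\,\partial u/\partial y} evaluated at each
#' wall, so its sign flips with the sign of the wall speed (for closed ends
#' the fluid adjacent to the tissue moves against the electrode, hence the
#' tissue-wall value is \eqn{-2\mu U/h}).
#'
#' @param gap a [gap_geometry()].
#' @param fluid a [fluid_properties()].
#' @param wall_speed electrode wall speed U (m/s); may be a vector.
#' @param tissue optional [tissue_properties()]; validated and deliberately
#'   unused (rigid-wall assumption).
#' @return A tibble with columns `tau_tissue` and `tau_electrode` (Pa),
#'   one row per element of `wall_speed`.
#' @examples
#' gp <- gap_geometry(side_gap = 50e-6)
#' fl <- interstitial_fluid(50e-3)
#' couette_wss(gp, fl, peak_speed(micromotion_waveform()))
#' @export
couette_wss <- function(gap, fluid, wall_speed, tissue = NULL) {
  check_gap(gap)
  check_fluid(fluid)
  check_finite(wall_speed, "wall_speed")
  if (!is.null(tissue) && !inherits(tissue, "tissue_properties")) {
    abort_invalid("`tissue` must be created by tissue_properties().")
  }
  mu_over_h <- fluid$dynamic_viscosity / gap$side_gap
  if (gap$end_condition == "closed") {
    tibble(tau_tissue = -2 * mu_over_h * wall_speed,
           tau_electrode = 4 * mu_over_h * wall_speed)
  } else {
    tibble(tau_tissue = mu_over_h * wall_speed,
           tau_electrode = mu_over_h * wall_speed)
  }
}

# wall shear series container ---------------------------------------------

new_wss_series <- function(time, tau_tissue, tau_electrode, period, solver,
                           extra_attrs = list()) {
  out <- tibble(time = time, tau_tissue = tau_tissue,
                tau_electrode = tau_electrode)
  attr(out, "peak_abs") <- max(abs(tau_tissue))
  attr(out, "cycle_avg_abs") <- mean(abs(tau_tissue))
  attr(out, "period") <- period
  attr(out, "solver") <- solver
  for (nm in names(extra_attrs)) attr(out, nm) <- extra_attrs[[nm]]
  class(out) <- c("wss_series", class(out))
  out
}

#' Summaries of a wall shear series
#'
#' `wss_peak()` returns the peak magnitude of the tissue-wall shear over the
#' returned cycle; `wss_cycle_avg()` the cycle-averaged magnitude. For a
#' single-sinusoid drive in the quasi-steady regime their ratio is `2/pi`.
#'
#' @param x a `wss_series` as returned by [wss_timeseries()] or
#'   [fd_gap_solver()].
#' @return a single number (Pa).
#' @export
wss_peak <- function(x) {
  stopifnot(inherits(x, "wss_series"))
  attr(x, "peak_abs")
}

#' @rdname wss_peak
#' @export
wss_cycle_avg <- function(x) {
  stopifnot(inherits(x, "wss_series"))
  attr(x, "cycle_avg_abs")
}

#' @export
print.wss_series <- function(x, ...) {
  cat(sprintf(
    "<wss_series> solver = %s, peak |tau| = %.4g Pa, cycle-avg |tau| = %.4g Pa\n",
    attr(x, "solver"), attr(x, "peak_abs"), attr(x, "cycle_avg_abs")))
  NextMethod()
}

warn_if_unsteady <- function(gap, fluid, waveform) {
  f_max <- max(waveform$components$frequency)
  alpha <- womersley_number(gap$side_gap, fluid, f_max)
  if (alpha >= 0.3) {
    warn(sprintf(
      paste0("Womersley number %.3g >= 0.3: the quasi-steady analytic model ",
             "may be inaccurate; consider fd_gap_solver()."), alpha),
      class = "perimotion_unsteady_warning")
  }
  invisible(alpha)
}

#' Analytic wall-shear time series over one micromotion cycle
#'
#' Applies the quasi-steady [couette_wss()] model pointwise to the wall
#' speed `U(t)` of a micromotion waveform, sampling one full fundamental
#' period on a uniform grid. Peak and cycle-averaged magnitudes of the
#' tissue-wall stress are attached as attributes (see [wss_peak()]).
#'
#' @inheritParams couette_wss
#' @param waveform a [micromotion_waveform()].
#' @param samples_per_period uniform samples over one period (>= 64).
#' @return A `wss_series` tibble: `time` (s), `tau_tissue`, `tau_electrode`
#'   (Pa, signed).
#' @examples
#' s <- wss_timeseries(gap_geometry(50e-6), interstitial_fluid(50e-3),
#'                     micromotion_waveform())
#' wss_peak(s)       # ~0.0942 Pa
#' wss_cycle_avg(s)  # ~0.060 Pa (= peak * 2/pi)
#' @export
wss_timeseries <- function(gap, fluid, waveform = micromotion_waveform(),
                           samples_per_period = 512L, tissue = NULL) {
  check_gap(gap)
  check_fluid(fluid)
  check_waveform(waveform)
  if (samples_per_period < 64L) {
    abort_invalid("`samples_per_period` must be >= 64.")
  }
  warn_if_unsteady(gap, fluid, waveform)
  period <- waveform$period
  n <- as.integer(samples_per_period)
  time <- seq(0, period, length.out = n + 1L)[seq_len(n)]
  u <- velocity(waveform, time)
  tau <- couette_wss(gap, fluid, u, tissue = tissue)
  new_wss_series(time, tau$tau_tissue, tau$tau_electrode, period,
                 solver = "analytic")
}

#' Squeeze-film shear under the electrode tip face
#'
#' Lubrication (thin-film Reynolds) model of the fluid layer between the
#' flat electrode tip (a rigid disc of radius `R`) and the tissue below it,
#' when the electrode motion has a component normal to that face. With film
#' thickness \eqn{g(t) = g_0 + x(t)}, radial volume conservation gives the
#' wall shear \deqn{\tau(r, t) = 3 \mu r |\dot g(t)| / g(t)^2,} zero on the
#' axis and maximal at the rim.
#'
#' @param tip_face_radius disc radius R (m).
#' @param mean_gap mean film thickness g0 (m); must exceed the peak normal
#'   displacement, otherwise the surfaces would touch.
#' @param waveform_normal a [micromotion_waveform()] for the normal motion.
#' @param fluid a [fluid_properties()].
#' @param r radial position(s) (m), 0 <= r <= R.
#' @param t time(s) (s). `r` and `t` are recycled to a common length.
#' @return wall shear stress magnitude (Pa) at (`r`, `t`).
#' @examples
#' squeeze_film_wss(50e-6, 100e-6, micromotion_waveform(),
#'                  interstitial_fluid(50e-3), r = 50e-6, t = 0)
#' @export
squeeze_film_wss <- function(tip_face_radius, mean_gap, waveform_normal,
                             fluid, r, t) {
  check_positive_scalar(tip_face_radius, "tip_face_radius")
  check_positive_scalar(mean_gap, "mean_gap")
  check_waveform(waveform_normal)
  check_fluid(fluid)
  check_finite(r, "r")
  check_finite(t, "t")
  if (any(r < 0) || any(r > tip_face_radius)) {
    abort_invalid("`r` must lie in [0, tip_face_radius].")
  }
  amp_sum <- sum(waveform_normal$components$amplitude)
  if (amp_sum >= mean_gap) {
    abort(
      sprintf(paste0("normal-motion amplitude (%g m) reaches the mean gap ",
                     "(%g m): squeeze film would make contact."),
             amp_sum, mean_gap),
      class = "perimotion_contact_singularity"
    )
  }
  g <- mean_gap + displacement(waveform_normal, t)
  gdot <- velocity(waveform_normal, t)
  3 * fluid$dynamic_viscosity * r * abs(gdot) / g^2
}
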