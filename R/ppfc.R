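#' Parallel-plate flow-chamber geometry
#'
#' A wide, shallow rectangular channel (width `b`, height `h`, aspect ratio
#' `b/h`) used to impose a defined wall shear stress on a cell monolayer via
#' plane-Poiseuille flow, \eqn{\tau_w = 6 Q \mu / (b h^2)}.
#'
#' @param width_b channel width b (m).
#' @param height_h channel height h (m); must satisfy `width_b > height_h`.
#' @return A `ppfc_channel` list with `width_b`, `height_h`, `aspect_ratio`.
#' @seealso [solve_channel()] to derive the geometry from a calibration
#'   point, [wss_from_flow()] for the dosimetry.
#' @export
ppfc_channel <- function(width_b, height_h) {
  check_positive_scalar(width_b, "width_b")
  check_positive_scalar(height_h, "height_h")
  if (width_b <= height_h) {
    abort_invalid("`width_b` must exceed `height_h` (wide shallow channel).")
  }
  structure(
    list(width_b = width_b, height_h = height_h,
         aspect_ratio = width_b / height_h),
    class = "ppfc_channel"
  )
}

#' @export
print.ppfc_channel <- function(x, ...) {
  cat(sprintf("<ppfc_channel> b = %.4g mm, h = %.4g um, b/h = %.4g\n",
              x$width_b * 1e3, m_to_um(x$height_h), x$aspect_ratio))
  invisible(x)
}

check_channel <- function(channel) {
  if (!inherits(channel, "ppfc_channel")) {
    abort_invalid("`channel` must be created by ppfc_channel() or solve_channel().")
  }
  invisible(channel)
}

#' Wall shear stress from flow rate (and its inverse)
#'
#' Plane-Poiseuille dosimetry of a wide rectangular channel:
#' \deqn{\tau_w = \frac{6 Q \mu}{b h^2}.}
#' `flow_for_wss()` is the exact inverse, returning the volumetric flow rate
#' that delivers a target wall shear stress.
#'
#' @param Q volumetric flow rate (m^3/s), > 0 (may be a positive vector).
#' @param fluid a [fluid_properties()].
#' @param channel a [ppfc_channel()].
#' @param target_wss target wall shear stress (Pa), > 0.
#' @return `wss_from_flow()`: wall shear stress (Pa); `flow_for_wss()`:
#'   flow rate (m^3/s).
#' @examples
#' ch <- solve_channel()
#' wss_from_flow(ml_min_to_m3s(4.49), culture_medium(), ch)   # 0.1 Pa
#' m3s_to_ml_min(flow_for_wss(0.5, culture_medium(), ch))     # 22.45
#' @export
wss_from_flow <- function(Q, fluid, channel) {
  check_finite(Q, "Q")
  if (any(Q < 0)) abort_invalid("`Q` must be non-negative.")
  check_fluid(fluid)
  check_channel(channel)
  6 * Q * fluid$dynamic_viscosity /
    (channel$width_b * channel$height_h^2)
}

#' @rdname wss_from_flow
#' @export
flow_for_wss <- function(target_wss, fluid, channel) {
  check_finite(target_wss, "target_wss")
  if (any(target_wss <= 0)) abort_invalid("`target_wss` must be > 0.")
  check_fluid(fluid)
  check_channel(channel)
  target_wss * channel$width_b * channel$height_h^2 /
    (6 * fluid$dynamic_viscosity)
}

#' Derive chamber dimensions from a calibration point
#'
#' Manufacturers quote the aspect ratio `b/h` and a calibrated
#' (flow rate, WSS) pair rather than the raw dimensions. This closes the
#' system: from \eqn{\tau = 6 Q \mu / (b h^2)} with \eqn{b = (b/h)\,h},
#' \deqn{h = \left(\frac{6 Q \mu}{\tau\, (b/h)}\right)^{1/3}.}
#' The defaults reproduce the chamber used for the astrocyte dosimetry:
#' aspect ratio 120, 4.49 mL/min of culture medium yielding 0.1 Pa, giving
#' h = 326.6 um and b = 39.19 mm (consistent with a 38 mm slide width).
#'
#' @param aspect_ratio target width/height ratio, > 1.
#' @param Q calibration flow rate (m^3/s).
#' @param fluid a [fluid_properties()].
#' @param target_wss calibration wall shear stress (Pa).
#' @return A [ppfc_channel()] satisfying
#'   `wss_from_flow(Q, fluid, channel) == target_wss` to 1e-12 relative.
#' @export
solve_channel <- function(aspect_ratio = 120, Q = ml_min_to_m3s(4.49),
                          fluid = culture_medium(), target_wss = 0.1) {
  check_positive_scalar(aspect_ratio, "aspect_ratio")
  if (aspect_ratio <= 1) {
    abort_invalid("`aspect_ratio` must exceed 1 (wide shallow channel).")
  }
  check_positive_scalar(Q, "Q")
  check_fluid(fluid)
  check_positive_scalar(target_wss, "target_wss")
  h <- (6 * Q * fluid$dynamic_viscosity /
          (target_wss * aspect_ratio))^(1 / 3)
  ppfc_channel(width_b = aspect_ratio * h, height_h = h)
}

#' Channel Reynolds number
#'
#' Convention: characteristic length = channel height `h`, mean speed
#' `u = Q/(b h)`, so \eqn{Re = \rho\,\bar u\,h/\mu = \rho Q / (\mu b)}.
#' This is the convention under which the 0.1 Pa condition of the default
#' chamber gives Re = 2.07; the hydraulic-diameter convention (2h for a
#' wide slot) would double it.
#'
#' @inheritParams wss_from_flow
#' @return dimensionless Reynolds number.
#' @export
reynolds_channel <- function(Q, fluid, channel) {
  check_finite(Q, "Q")
  if (any(Q < 0)) abort_invalid("`Q` must be non-negative.")
  check_fluid(fluid)
  check_channel(channel)
  fluid$density * Q / (fluid$dynamic_viscosity * channel$width_b)
}

#' Flow condition in a parallel-plate chamber
#'
#' Bundles a flow rate with its derived dose metrics: wall shear stress,
#' Reynolds number and (for oscillatory drive) Womersley number based on the
#' half-height.
#'
#' @inheritParams wss_from_flow
#' @param frequency oscillation frequency (Hz); 0 for steady flow.
#' @return A one-row tibble: `flow_rate` (m^3/s), `wss` (Pa), `reynolds`,
#'   `womersley`, `frequency` (Hz).
#' @examples
#' ppfc_condition(ml_min_to_m3s(4.49), culture_medium(), solve_channel())
#' @export
ppfc_condition <- function(Q, fluid, channel, frequency = 0.5) {
  check_positive_scalar(Q, "Q")
  check_fluid(fluid)
  check_channel(channel)
  check_nonneg_scalar(frequency, "frequency")
  alpha <- if (frequency > 0) {
    womersley_number(channel$height_h / 2, fluid, frequency)
  } else {
    0
  }
  tibble(
    flow_rate = Q,
    wss = wss_from_flow(Q, fluid, channel),
    reynolds = reynolds_channel(Q, fluid, channel),
    womersley = alpha,
    frequency = frequency
  )
}

#' Flow-regime homogeneity report
#'
#' Checks the two dimensionless criteria under which an oscillatory
#' chamber flow delivers a spatially homogeneous, quasi-steady wall shear:
#' the half-height Womersley number below 1 (profile follows the flow-rate
#' modulation quasi-statically) and the Reynolds number below the
#' plane-channel transition heuristic 1400 (laminar).
#'
#' @param condition a one-row tibble from [ppfc_condition()].
#' @return A one-row tibble: `womersley`, `reynolds`, `quasi_steady`,
#'   `laminar`.
#' @export
homogeneity_report <- function(condition) {
  req <- c("womersley", "reynolds")
  if (!is.data.frame(condition) || !all(req %in% names(condition))) {
    abort_invalid("`condition` must come from ppfc_condition().")
  }
  tibble(
    womersley = condition$womersley,
    reynolds = condition$reynolds,
    quasi_steady = condition$womersley < 1,
    laminar = condition$reynolds < 1400
  )
}
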