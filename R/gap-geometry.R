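#' Peri-electrode gap geometry
#'
#' Geometry of the fluid-filled void between an implanted electrode and the
#' surrounding tissue: the electrode diameter, the per-side electrode-tissue
#' distance (the gap `h` across which the shear develops), and whether the
#' cavity ends are closed (sealed void, the default: end walls force the net
#' cross-gap flux to zero) or open. An optional tip face supports the
#' squeeze-film term ([squeeze_film_wss()]).
#'
#' @param side_gap per-side electrode-tissue distance h (m), > 0.
#' @param electrode_diameter electrode diameter (m), default 100 um.
#' @param end_condition `"closed"` (sealed cavity, zero net flux) or
#'   `"open"`.
#' @param tip_face_radius optional tip face radius (m); defaults to the
#'   electrode radius.
#' @param tip_face_gap optional fluid gap under the tip face (m).
#' @return A `gap_geometry` list.
#' @examples
#' gap_geometry(side_gap = 50e-6)
#' @export
gap_geometry <- function(side_gap, electrode_diameter = 100e-6,
                         end_condition = c("closed", "open"),
                         tip_face_radius = NULL, tip_face_gap = NULL) {
  check_positive_scalar(side_gap, "side_gap")
  check_positive_scalar(electrode_diameter, "electrode_diameter")
  end_condition <- match.arg(end_condition)
  if (is.null(tip_face_radius)) tip_face_radius <- electrode_diameter / 2
  check_positive_scalar(tip_face_radius, "tip_face_radius")
  if (!is.null(tip_face_gap)) check_positive_scalar(tip_face_gap, "tip_face_gap")
  structure(
    list(side_gap = side_gap,
         electrode_diameter = electrode_diameter,
         end_condition = end_condition,
         tip_face_radius = tip_face_radius,
         tip_face_gap = tip_face_gap),
    class = "gap_geometry"
  )
}

#' @export
print.gap_geometry <- function(x, ...) {
  cat(sprintf(
    "<gap_geometry> h = %g um, electrode d = %g um, ends %s\n",
    m_to_um(x$side_gap), m_to_um(x$electrode_diameter), x$end_condition))
  invisible(x)
}

check_gap <- function(gap) {
  if (!inherits(gap, "gap_geometry")) {
    abort(
      "`gap` must be created by gap_geometry().",
      class = "perimotion_invalid_geometry"
    )
  }
  invisible(gap)
}

#' Brain tissue mechanical properties
#'
#' Recorded for configuration completeness only: the flow models treat the
#' tissue wall as rigid, so these constants are consumed by no flow
#' computation. Defaults are the literature values for brain tissue
#' (density 1060 kg/m^3, Young's modulus 6 kPa, Poisson's ratio 0.45).
#'
#' @param density tissue density (kg/m^3).
#' @param youngs_modulus Young's modulus (Pa).
#' @param poisson_ratio Poisson's ratio, in (0, 0.5].
#' @return A `tissue_properties` list.
#' @export
tissue_properties <- function(density = 1060, youngs_modulus = 6e3,
                              poisson_ratio = 0.45) {
  check_positive_scalar(density, "density")
  check_positive_scalar(youngs_modulus, "youngs_modulus")
  check_positive_scalar(poisson_ratio, "poisson_ratio")
  if (poisson_ratio > 0.5) abort_invalid("`poisson_ratio` must be <= 0.5.")
  structure(
    list(density = density, youngs_modulus = youngs_modulus,
         poisson_ratio = poisson_ratio),
    class = "tissue_properties"
  )
}
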