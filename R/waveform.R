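#' Periodic electrode micromotion waveform
#'
#' Describes the cyclic displacement of an electrode relative to the
#' surrounding tissue as a sum of sinusoidal components,
#' \deqn{x(t) = \sum_j A_j \sin(2\pi f_j t + \phi_j).}
#' The default is the respiration-driven motion used throughout the package:
#' a single component of amplitude 15 um (30 um peak-to-peak) at 0.5 Hz.
#' Multi-component waveforms (e.g. an added cardiac harmonic) are supported
#' for synthetic-data generation.
#'
#' @param amplitude numeric vector of component amplitudes (m), all > 0.
#' @param frequency numeric vector of component frequencies (Hz), all > 0.
#' @param phase numeric vector of component phases (rad); recycled to the
#'   length of `amplitude`. Peak and cycle-averaged shear summaries are
#'   phase-invariant, so the default 0 is a pure convention.
#' @return An object of class `micromotion_waveform`: a list with a
#'   `components` tibble (`amplitude`, `frequency`, `phase`) and the
#'   fundamental `period` (s).
#' @examples
#' wf <- micromotion_waveform()          # 15 um at 0.5 Hz
#' displacement(wf, c(0, 0.5, 1))        # 0, +15 um, 0
#' peak_speed(wf)                        # 2*pi*0.5*15e-6 m/s
#' @export
micromotion_waveform <- function(amplitude = 15e-6, frequency = 0.5,
                                 phase = 0) {
  check_finite(amplitude, "amplitude")
  check_finite(frequency, "frequency")
  check_finite(phase, "phase")
  if (length(amplitude) != length(frequency)) {
    abort_invalid("`amplitude` and `frequency` must have the same length.")
  }
  if (any(amplitude < 0)) abort_invalid("every `amplitude` must be >= 0.")
  if (any(frequency <= 0)) abort_invalid("every `frequency` must be > 0.")
  phase <- rep_len(phase, length(amplitude))
  comp <- tibble(amplitude = as.numeric(amplitude),
                 frequency = as.numeric(frequency),
                 phase = as.numeric(phase))
  structure(
    list(components = comp, period = 1 / rate_gcd(comp$frequency)),
    class = "micromotion_waveform"
  )
}

# gcd of a set of positive rates, tolerant to floating-point frequencies;
# the waveform repeats with period 1/gcd (2 s for the 0.5 Hz default)
rate_gcd <- function(f, tol = 1e-9) {
  g <- f[1]
  for (x in f[-1]) {
    a <- max(g, x); b <- min(g, x)
    while (b > tol * max(f)) {
      r <- a - floor(a / b + tol) * b
      a <- b
      b <- r
    }
    g <- a
  }
  g
}

#' @export
print.micromotion_waveform <- function(x, ...) {
  cat("<micromotion_waveform>\n")
  cat(sprintf("  components: %d, period: %g s\n",
              nrow(x$components), x$period))
  comp <- x$components
  for (i in seq_len(nrow(comp))) {
    cat(sprintf("  A = %g um, f = %g Hz, phase = %g rad\n",
                m_to_um(comp$amplitude[i]), comp$frequency[i], comp$phase[i]))
  }
  invisible(x)
}

check_waveform <- function(waveform) {
  if (!inherits(waveform, "micromotion_waveform")) {
    abort_invalid("`waveform` must be created by micromotion_waveform().")
  }
  invisible(waveform)
}

#' Electrode displacement and velocity
#'
#' Evaluate the micromotion displacement `x(t)` (m) or its time derivative,
#' the wall speed `U(t)` (m/s), at times `t`.
#'
#' @param waveform a [micromotion_waveform()].
#' @param t numeric vector of times (s).
#' @return numeric vector, same length as `t`.
#' @examples
#' wf <- micromotion_waveform()
#' velocity(wf, 0)    # peak speed 2*pi*f*A
#' @export
displacement <- function(waveform, t) {
  check_waveform(waveform)
  check_finite(t, "t")
  comp <- waveform$components
  out <- numeric(length(t))
  for (i in seq_len(nrow(comp))) {
    out <- out + comp$amplitude[i] *
      sin(2 * pi * comp$frequency[i] * t + comp$phase[i])
  }
  out
}

#' @rdname displacement
#' @export
velocity <- function(waveform, t) {
  check_waveform(waveform)
  check_finite(t, "t")
  comp <- waveform$components
  out <- numeric(length(t))
  for (i in seq_len(nrow(comp))) {
    w <- 2 * pi * comp$frequency[i]
    out <- out + comp$amplitude[i] * w * cos(w * t + comp$phase[i])
  }
  out
}

#' Peak wall speed over one waveform period
#'
#' For a single sinusoid this is exactly `2*pi*f*A`; for multi-harmonic
#' waveforms the maximum of `|U(t)|` is located on a dense grid over one
#' fundamental period.
#'
#' @inheritParams displacement
#' @param n grid resolution used for multi-harmonic waveforms.
#' @return peak speed (m/s).
#' @export
peak_speed <- function(waveform, n = 8192L) {
  check_waveform(waveform)
  comp <- waveform$components
  if (nrow(comp) == 1L) {
    return(comp$amplitude * 2 * pi * comp$frequency)
  }
  t <- seq(0, waveform$period, length.out = n + 1L)[-(n + 1L)]
  max(abs(velocity(waveform, t)))
}

#' Fluid properties
#'
#' Density and dynamic viscosity of the working fluid. Two presets cover the
#' fluids used in this problem: brain interstitial fluid (density
#' 1006 kg/m^3, viscosity 1.2--100 mPa s depending on tissue state) and
#' DMEM/F12 culture medium (1009 kg/m^3, 0.930 mPa s) for the flow chamber.
#'
#' @param density fluid density (kg/m^3), > 0.
#' @param dynamic_viscosity dynamic viscosity (Pa s), > 0.
#' @return A `fluid_properties` list with `density`, `dynamic_viscosity` and
#'   the derived `kinematic_viscosity` (m^2/s).
#' @examples
#' interstitial_fluid(viscosity = 50e-3)
#' culture_medium()
#' @export
fluid_properties <- function(density, dynamic_viscosity) {
  check_positive_scalar(density, "density")
  check_positive_scalar(dynamic_viscosity, "dynamic_viscosity")
  structure(
    list(density = density,
         dynamic_viscosity = dynamic_viscosity,
         kinematic_viscosity = dynamic_viscosity / density),
    class = "fluid_properties"
  )
}

#' @rdname fluid_properties
#' @param viscosity dynamic viscosity (Pa s) for the interstitial preset.
#' @export
interstitial_fluid <- function(viscosity = 50e-3) {
  fluid_properties(density = 1006, dynamic_viscosity = viscosity)
}

#' @rdname fluid_properties
#' @export
culture_medium <- function() {
  fluid_properties(density = 1009, dynamic_viscosity = 0.930e-3)
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("<fluid_properties> rho = %g kg/m^3, mu = %g mPa s\n",
              x$density, pas_to_mpas(x$dynamic_viscosity)))
  invisible(x)
}

check_fluid <- function(fluid) {
  if (!inherits(fluid, "fluid_properties")) {
    abort_invalid("`fluid` must be created by fluid_properties().")
  }
  invisible(fluid)
}

#' Womersley number of an oscillatory flow
#'
#' \deqn{\alpha = L \sqrt{2\pi f \rho / \mu}.}
#' When `alpha^2 << 1` viscous diffusion is fast compared with the
#' oscillation and the velocity profile is quasi-steady, which is the regime
#' the analytic gap-flow and chamber models assume. Convention for the
#' characteristic length `L`: the full gap width for the peri-electrode
#' channel, the half-height for the parallel-plate chamber.
#'
#' @param char_length characteristic length (m), > 0.
#' @param fluid a [fluid_properties()].
#' @param frequency oscillation frequency (Hz), > 0.
#' @return dimensionless Womersley number.
#' @examples
#' womersley_number(50e-6, interstitial_fluid(50e-3), 0.5)  # ~0.0126
#' @export
womersley_number <- function(char_length, fluid, frequency) {
  check_positive_scalar(char_length, "char_length")
  check_fluid(fluid)
  check_positive_scalar(frequency, "frequency")
  char_length * sqrt(2 * pi * frequency * fluid$density /
                       fluid$dynamic_viscosity)
}
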