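#' Unit conversion helpers
#'
#' Convenience converters between the bench units used in the neural-implant
#' literature (micrometres, millipascal-seconds, millilitres per minute) and
#' the SI units (m, Pa s, m^3 s^-1) used by every function in this package.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @examples
#' um_to_m(15)            # 1.5e-05 m
#' mpas_to_pas(50)        # 0.05 Pa s
#' ml_min_to_m3s(4.49)    # 7.483e-08 m^3 s^-1
#' @name units
NULL

#' @rdname units
#' @export
um_to_m <- function(x) x * 1e-6

#' @rdname units
#' @export
m_to_um <- function(x) x * 1e6

#' @rdname units
#' @export
mpas_to_pas <- function(x) x * 1e-3

#' @rdname units
#' @export
pas_to_mpas <- function(x) x * 1e3

#' @rdname units
#' @export
ml_min_to_m3s <- function(x) x * 1e-6 / 60

#' @rdname units
#' @export
m3s_to_ml_min <- function(x) x * 60 * 1e6

# shared input validation -------------------------------------------------

abort_invalid <- function(msg, ...) {
  abort(msg, class = "perimotion_invalid_parameter", ...)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort_invalid(sprintf("`%s` must be a single finite positive number.", name))
  }
  invisible(x)
}

check_nonneg_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    abort_invalid(sprintf("`%s` must be a single finite non-negative number.", name))
  }
  invisible(x)
}

check_finite <- function(x, name) {
  if (!is.numeric(x) || !all(is.finite(x))) {
    abort_invalid(sprintf("`%s` must be finite numeric.", name))
  }
  invisible(x)
}
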