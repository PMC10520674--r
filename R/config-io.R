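#' Default configuration
#'
#' The full set of model inputs as a nested list, in the bench units used
#' on the command line (um, mPa s, mL/min). Sections: `micromotion`,
#' `fluid`, `geometry`, `ppfc`, `void`, `sweep`, `synth`. Values default to
#' the study conditions of the models in this package: respiration-driven
#' motion of 15 um at 0.5 Hz, interstitial fluid of density 1006 kg/m^3,
#' culture medium of 1009 kg/m^3 and 0.930 mPa s, a chamber of aspect
#' ratio 120 calibrated so 4.49 mL/min delivers 0.1 Pa, and a 0.1 Pa
#' void-expansion threshold.
#'
#' @return nested list.
#' @export
default_config <- function() {
  list(
    micromotion = list(
      components = list(
        list(amplitude_um = 15, frequency_hz = 0.5, phase_rad = 0)
      )
    ),
    fluid = list(
      interstitial = list(density_kg_m3 = 1006, viscosity_mpa_s = 50),
      medium = list(density_kg_m3 = 1009, viscosity_mpa_s = 0.93)
    ),
    geometry = list(
      electrode_diameter_um = 100,
      side_gap_um = 50,
      end_condition = "closed"
    ),
    ppfc = list(
      aspect_ratio = 120,
      calibration_flow_ml_min = 4.49,
      calibration_wss_pa = 0.1,
      frequency_hz = 0.5
    ),
    void = list(
      tau_threshold_pa = 0.1,
      rate_k_m_per_pa_s = 1e-9,
      initial_gap_um = 10,
      wss_metric = "peak"
    ),
    sweep = list(
      gap_um = seq(10, 150, length.out = 8),
      viscosity_mpa_s = exp(seq(log(1.2), log(100), length.out = 8)),
      end_condition = "closed"
    ),
    synth = list(
      respiratory = list(amplitude_um = 15, frequency_hz = 0.5),
      cardiac = list(amplitude_um = 3, frequency_hz = 5),
      displacement_noise_sd_um = 0.5,
      wss_noise_rel_sd = 0.05,
      n_samples = 1000L,
      seed = 1L
    )
  )
}

#' Read and write JSON configurations
#'
#' `write_config()` serialises a configuration list to JSON at full
#' numeric precision; `read_config()` parses and validates it against the
#' schema of [default_config()]. Keys absent from the file fall back to
#' their defaults; unknown keys raise a validation error naming the
#' offending field path. `read_config(write_config(default_config()))`
#' reproduces the defaults exactly.
#'
#' @param config a configuration list shaped like [default_config()].
#' @param path file path.
#' @return `read_config()`: the validated, default-completed list.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path),
          class = "perimotion_config_error")
  }
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  validate_config(cfg)
}

#' @rdname write_config
#' @export
validate_config <- function(config) {
  schema <- default_config()
  check_keys(config, schema, path = character())
  merge_defaults(schema, config)
}

check_keys <- function(node, schema, path) {
  if (!is.list(node)) return(invisible())
  nms <- names(node)
  if (is.null(nms)) return(invisible())      # unnamed arrays (components)
  unknown <- setdiff(nms, names(schema))
  if (length(unknown) > 0) {
    abort(sprintf("unknown configuration key: %s",
                  paste(c(path, unknown[1]), collapse = ".")),
          class = "perimotion_config_error")
  }
  for (nm in nms) {
    if (is.list(schema[[nm]]) && !is.null(names(schema[[nm]]))) {
      check_keys(node[[nm]], schema[[nm]], c(path, nm))
    }
  }
  invisible()
}

merge_defaults <- function(schema, node) {
  if (!is.list(schema) || is.null(names(schema))) {
    return(if (is.null(node)) schema else node)
  }
  out <- schema
  for (nm in names(schema)) {
    if (!is.null(node[[nm]])) {
      out[[nm]] <- merge_defaults(schema[[nm]], node[[nm]])
    }
  }
  out
}

#' Write and read result tables as CSV
#'
#' Thin wrappers around readr that write full-precision CSV (so reloading
#' reproduces the table values exactly) for sweep results, wall-shear
#' series, trajectories, or any tibble.
#'
#' @param x a data frame.
#' @param path file path.
#' @return `read_result_csv()`: a tibble.
#' @export
write_result_csv <- function(x, path) {
  if (!is.data.frame(x)) abort_invalid("`x` must be a data frame.")
  readr::write_csv(as_tibble(as.data.frame(x)), path)
  invisible(path)
}

#' @rdname write_result_csv
#' @export
read_result_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
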