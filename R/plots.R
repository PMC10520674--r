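#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a wall-shear time series
#'
#' Signed tissue- and electrode-wall shear stress over the returned cycle.
#'
#' @param object a `wss_series` from [wss_timeseries()] or
#'   [fd_gap_solver()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot wss_series
#' @export
autoplot.wss_series <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              cols = c("tau_tissue", "tau_electrode"),
                              names_to = "wall", values_to = "tau")
  long$wall <- sub("^tau_", "", long$wall)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$tau,
                                     colour = .data$wall)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "wall shear stress (Pa)",
                  colour = NULL,
                  title = sprintf("Oscillatory gap-flow WSS (%s solver)",
                                  attr(object, "solver"))) +
    ggplot2::theme_minimal()
}

#' Heatmap of the gap-by-viscosity shear sweep
#'
#' @param object a `sweep_result` from [run_sweep()].
#' @param metric `"peak"` or `"cycle_avg"` tissue-wall magnitude.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, metric = c("peak", "cycle_avg"),
                                  ...) {
  metric <- match.arg(metric)
  col <- if (metric == "peak") "wss_peak" else "wss_cycle_avg"
  df <- as_tibble(object)
  df$wss <- df[[col]]
  ggplot2::ggplot(df, ggplot2::aes(x = m_to_um(.data$gap),
                                   y = pas_to_mpas(.data$viscosity),
                                   fill = .data$wss)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::labs(x = "electrode-tissue gap (µm)",
                  y = "viscosity (mPa s)",
                  fill = sprintf("%s |WSS| (Pa)", metric)) +
    ggplot2::theme_minimal()
}

#' Plot a void-expansion trajectory
#'
#' Per-side gap growth (um) and the concurrent wall shear stress decay
#' toward the threshold.
#'
#' @param object a `void_trajectory` from [simulate_expansion()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot void_trajectory
#' @export
autoplot.void_trajectory <- function(object, ...) {
  df <- as_tibble(object)
  long <- tidyr::pivot_longer(
    tibble(time = df$time, `gap (µm)` = m_to_um(df$gap),
           `WSS (Pa)` = df$wss),
    cols = -"time", names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "Peri-electrode void expansion") +
    ggplot2::theme_minimal()
}
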