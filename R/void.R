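#' Parameters of the void-expansion model
#'
#' Minimal model of peri-electrode void growth: tissue recedes while the
#' micromotion-induced wall shear stress exceeds a reactivity threshold
#' `tau_threshold` (default 0.1 Pa), so the per-side gap `g` evolves as
#' \deqn{dg/dt = k \max(0,\ \tau(g) - \tau_c),}
#' with \eqn{\tau(g)} the closed-cavity Couette tissue-wall stress at gap
#' `g` (peak or cycle-averaged magnitude, per `wss_metric`). Only the steady
#' state is physically grounded; the rate constant `k` sets the time scale
#' and is not identifiable from steady-state observations.
#'
#' @param rate_k regression-rate constant k (m Pa^-1 s^-1), > 0.
#' @param initial_gap starting per-side gap (m), > 0.
#' @param tau_threshold reactivity threshold tau_c (Pa), default 0.1.
#' @param wss_metric `"peak"` (default; reproduces the 0.1 Pa benchmark) or
#'   `"cycle_avg"` for sensitivity analysis.
#' @param fluid a [fluid_properties()]; default interstitial fluid at
#'   50 mPa s.
#' @param waveform a [micromotion_waveform()].
#' @param electrode_diameter electrode diameter (m), default 100 um.
#' @return A `void_params` list.
#' @export
void_params <- function(rate_k, initial_gap, tau_threshold = 0.1,
                        wss_metric = c("peak", "cycle_avg"),
                        fluid = interstitial_fluid(),
                        waveform = micromotion_waveform(),
                        electrode_diameter = 100e-6) {
  check_positive_scalar(rate_k, "rate_k")
  check_positive_scalar(initial_gap, "initial_gap")
  check_positive_scalar(tau_threshold, "tau_threshold")
  wss_metric <- match.arg(wss_metric)
  check_fluid(fluid)
  check_waveform(waveform)
  check_positive_scalar(electrode_diameter, "electrode_diameter")
  structure(
    list(rate_k = rate_k, initial_gap = initial_gap,
         tau_threshold = tau_threshold, wss_metric = wss_metric,
         fluid = fluid, waveform = waveform,
         electrode_diameter = electrode_diameter),
    class = "void_params"
  )
}

# speed scale of the waveform under the chosen metric: peak |U| or the
# cycle-averaged |U| (2/pi of the peak for a pure sinusoid)
metric_speed <- function(waveform, wss_metric, n = 8192L) {
  if (wss_metric == "peak") return(peak_speed(waveform))
  t <- seq(0, waveform$period, length.out = n + 1L)[-(n + 1L)]
  mean(abs(velocity(waveform, t)))
}

# closed-cavity tissue-wall WSS magnitude at per-side gap g; the speed
# scale is precomputed once per simulation
wss_at_gap <- function(g, params, speed = metric_speed(params$waveform,
                                                       params$wss_metric)) {
  2 * params$fluid$dynamic_viscosity * speed / g
}

#' Steady-state per-side gap of the expanding void
#'
#' The gap at which the micromotion-induced wall shear stress has fallen to
#' the reactivity threshold and expansion stops. For the closed-cavity
#' Couette model the stress is \eqn{\tau(g) = 2\mu S/g} (S the peak or
#' cycle-averaged wall speed), so the fixed point is the closed form
#' \deqn{g^* = 2 \mu S / \tau_c.}
#' If the stress at `initial_gap` is already at or below the threshold the
#' void does not expand and `initial_gap` is returned.
#'
#' @param params a [void_params()].
#' @return steady-state per-side gap (m).
#' @examples
#' p <- void_params(rate_k = 1e-9, initial_gap = 10e-6)
#' m_to_um(steady_state_gap(p))                      # ~47.1 um
#' m_to_um(p$electrode_diameter + 2 * steady_state_gap(p))  # ~194 um void
#' @export
steady_state_gap <- function(params) {
  if (!inherits(params, "void_params")) {
    abort_invalid("`params` must be created by void_params().")
  }
  if (wss_at_gap(params$initial_gap, params) <= params$tau_threshold) {
    return(params$initial_gap)
  }
  2 * params$fluid$dynamic_viscosity *
    metric_speed(params$waveform, params$wss_metric) / params$tau_threshold
}

#' Simulate void expansion to steady state
#'
#' Integrates \eqn{dg/dt = k \max(0, \tau(g) - \tau_c)} by explicit Euler
#' with step-halving acceptance on the gap increment (adequate for this
#' monotone scalar ODE). The stress is evaluated quasi-statically at the
#' instantaneous gap. The trajectory converges to [steady_state_gap()]
#' independent of `k` (which only sets the time scale) and of the initial
#' gap, provided it starts below the fixed point.
#'
#' @param params a [void_params()].
#' @param t_end integration end time (s); default 30 relaxation times
#'   \eqn{g^*/(k \tau_c)}. A warning is issued below 10 relaxation times.
#' @param dt output sampling interval (s); default `t_end/400`. Integration
#'   substeps are refined independently of `dt`.
#' @return A `void_trajectory` tibble (`time` s, `gap` m, `wss` Pa) with
#'   attributes `steady_state_gap` (terminal gap, m), `void_diameter`
#'   (electrode diameter + 2 gap, m) and `converged` (terminal stress within
#'   1e-6 relative of the threshold, or no expansion).
#' @export
simulate_expansion <- function(params, t_end = NULL, dt = NULL) {
  if (!inherits(params, "void_params")) {
    abort_invalid("`params` must be created by void_params().")
  }
  g_star <- steady_state_gap(params)
  relax <- g_star / (params$rate_k * params$tau_threshold)
  if (is.null(t_end)) t_end <- 30 * relax
  check_positive_scalar(t_end, "t_end")
  if (t_end < 10 * relax) {
    warn(sprintf(
      "t_end = %.3g s is under 10 relaxation times (%.3g s); the trajectory may not converge.",
      t_end, relax), class = "perimotion_short_horizon_warning")
  }
  if (is.null(dt)) dt <- t_end / 400
  check_positive_scalar(dt, "dt")

  speed <- metric_speed(params$waveform, params$wss_metric)
  rate <- function(g) {
    params$rate_k * max(0, wss_at_gap(g, params, speed) - params$tau_threshold)
  }

  out_t <- seq(0, t_end, by = dt)
  if (out_t[length(out_t)] < t_end) out_t <- c(out_t, t_end)
  gap <- numeric(length(out_t))
  gap[1] <- params$initial_gap
  tol <- 1e-8 * g_star
  g <- params$initial_gap
  for (i in seq_along(out_t)[-1]) {
    t_cur <- out_t[i - 1]
    t_next <- out_t[i]
    dt_sub <- t_next - t_cur
    while (t_cur < t_next - 1e-12 * t_end) {
      dt_try <- min(dt_sub, t_next - t_cur)
      repeat {
        g_full <- g + dt_try * rate(g)
        g_half <- g + dt_try / 2 * rate(g)
        g_two <- g_half + dt_try / 2 * rate(g_half)
        if (abs(g_full - g_two) <= tol || dt_try <= 1e-12 * t_end) break
        dt_try <- dt_try / 2
      }
      g <- g_two
      t_cur <- t_cur + dt_try
      dt_sub <- dt_try * 2          # allow the substep to grow back
    }
    gap[i] <- g
  }

  wss <- wss_at_gap(gap, params, speed)
  g_end <- gap[length(gap)]
  converged <- wss_at_gap(params$initial_gap, params, speed) <= params$tau_threshold ||
    abs(wss[length(wss)] - params$tau_threshold) / params$tau_threshold <= 1e-6
  out <- tibble(time = out_t, gap = gap, wss = wss)
  attr(out, "steady_state_gap") <- g_end
  attr(out, "void_diameter") <- params$electrode_diameter + 2 * g_end
  attr(out, "converged") <- converged
  class(out) <- c("void_trajectory", class(out))
  out
}

#' @export
print.void_trajectory <- function(x, ...) {
  cat(sprintf(
    "<void_trajectory> terminal gap = %.4g um, void diameter = %.4g um, converged: %s\n",
    m_to_um(attr(x, "steady_state_gap")), m_to_um(attr(x, "void_diameter")),
    attr(x, "converged")))
  NextMethod()
}
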