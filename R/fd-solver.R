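#' Unsteady finite-difference solver for the oscillatory gap flow
#'
#' Solves the 1-D unsteady Stokes problem across the peri-electrode gap,
#' \deqn{\partial u/\partial t = \nu\, \partial^2 u/\partial y^2 - G(t)/\rho,
#'   \quad y \in [0, h],}
#' with the tissue wall fixed (`u(0,t) = 0`) and the electrode wall moving
#' with the micromotion speed (`u(h,t) = U(t)`). For a sealed cavity
#' ("closed" ends) the axial pressure gradient `G(t)` is determined at every
#' time step so that the cross-gap flux \eqn{\int_0^h u\,dy} vanishes
#' exactly (linear superposition of two tridiagonal solves); for open ends
#' `G = 0`. The flow is laminar throughout: at the micromotion Reynolds
#' numbers of this problem (well below 1) no turbulence model is
#' appropriate.
#'
#' Time integration is Crank-Nicolson (second order); space is a uniform
#' second-order grid; the wall stress uses a one-sided second-order
#' derivative so the stress converges at the same order as the field. The
#' first `n_periods - 1` periods are discarded as start-up transient and the
#' returned series covers the last full period.
#'
#' @inheritParams wss_timeseries
#' @param n_points number of grid points across the gap (>= 51).
#' @param steps_per_period time steps per waveform period (>= 200).
#' @param n_periods number of periods to integrate (>= 5).
#' @return A `wss_series` tibble (`time`, `tau_tissue`, `tau_electrode`)
#'   covering the last period, with attributes `peak_abs`, `cycle_avg_abs`,
#'   `flux_residual` (max of `|int u dy| / (h max|u|)` over all steps) and
#'   `womersley`.
#' @examples
#' \donttest{
#' s <- fd_gap_solver(gap_geometry(50e-6), interstitial_fluid(50e-3),
#'                    micromotion_waveform(), n_points = 101)
#' wss_peak(s)   # within 1% of the quasi-steady 2*mu*U/h = 0.0942 Pa
#' }
#' @export
fd_gap_solver <- function(gap, fluid, waveform = micromotion_waveform(),
                          n_points = 201L, steps_per_period = 400L,
                          n_periods = 5L, tissue = NULL) {
  check_gap(gap)
  check_fluid(fluid)
  check_waveform(waveform)
  if (n_points < 51L) abort_invalid("`n_points` must be >= 51.")
  if (steps_per_period < 200L) abort_invalid("`steps_per_period` must be >= 200.")
  if (n_periods < 5L) abort_invalid("`n_periods` must be >= 5.")
  if (!is.null(tissue) && !inherits(tissue, "tissue_properties")) {
    abort_invalid("`tissue` must be created by tissue_properties().")
  }

  h <- gap$side_gap
  nu <- fluid$kinematic_viscosity
  mu <- fluid$dynamic_viscosity
  rho <- fluid$density
  closed <- gap$end_condition == "closed"
  period <- waveform$period

  n <- as.integer(n_points)
  m <- n - 2L                       # interior unknowns
  dy <- h / (n - 1)
  dt <- period / steps_per_period
  n_steps <- as.integer(n_periods) * as.integer(steps_per_period)
  r <- nu * dt / (2 * dy^2)

  # Thomas factorisation of the constant Crank-Nicolson matrix
  # (diag 1 + 2r, off-diagonals -r); den[] is precomputed once.
  den <- numeric(m)
  den[1] <- 1 + 2 * r
  for (i in 2:m) den[i] <- (1 + 2 * r) - r^2 / den[i - 1]

  solve_tridiag <- function(d) {
    dp <- numeric(m)
    dp[1] <- d[1] / den[1]
    for (i in 2:m) dp[i] <- (d[i] + r * dp[i - 1]) / den[i]
    x <- numeric(m)
    x[m] <- dp[m]
    for (i in (m - 1):1) x[i] <- dp[i] + r * x[i + 1] / den[i]
    x
  }

  # pressure-response field: A w = -dt/(2 rho) * 1, zero wall values
  w_field <- if (closed) solve_tridiag(rep(-dt / (2 * rho), m)) else NULL
  flux_w <- if (closed) dy * sum(w_field) else NA_real_

  # start from the quasi-steady profile at t = 0 to shorten the transient
  y <- seq(0, h, length.out = n)
  u0_wall <- velocity(waveform, 0)
  u <- if (closed) {
    u0_wall * y / h + 3 * u0_wall * (y^2 - y * h) / h^2
  } else {
    u0_wall * y / h
  }
  g_prev <- if (closed) 6 * mu * u0_wall / h^2 else 0

  tau_tissue <- numeric(n_steps)
  tau_electrode <- numeric(n_steps)
  times <- numeric(n_steps)
  flux_resid <- 0

  for (k in seq_len(n_steps)) {
    t_new <- k * dt
    u_wall <- velocity(waveform, t_new)
    ui <- u[2:(n - 1L)]
    d <- ui + r * (u[3:n] - 2 * ui + u[1:(n - 2L)]) - dt * g_prev / (2 * rho)
    d[m] <- d[m] + r * u_wall
    v <- solve_tridiag(d)
    if (closed) {
      flux_v <- dy * (sum(v) + 0.5 * u_wall)
      g_new <- -flux_v / flux_w
      ui_new <- v + g_new * w_field
    } else {
      g_new <- 0
      ui_new <- v
    }
    u <- c(0, ui_new, u_wall)
    if (!all(is.finite(u))) {
      abort(
        sprintf(paste0("finite-difference solution diverged at step %d ",
                       "(diffusion number nu*dt/dy^2 = %.3g)."), k, 2 * r),
        class = "perimotion_solver_failure"
      )
    }
    if (closed) {
      u_max <- max(abs(u))
      if (u_max > 0) {
        resid <- abs(dy * (sum(ui_new) + 0.5 * u_wall)) / (h * u_max)
        flux_resid <- max(flux_resid, resid)
      }
    }
    g_prev <- g_new
    times[k] <- t_new
    tau_tissue[k] <- mu * (4 * u[2] - u[3]) / (2 * dy)
    tau_electrode[k] <- mu * (3 * u[n] - 4 * u[n - 1L] + u[n - 2L]) / (2 * dy)
  }

  keep <- (n_steps - steps_per_period + 1L):n_steps
  new_wss_series(
    times[keep], tau_tissue[keep], tau_electrode[keep], period,
    solver = "fd",
    extra_attrs = list(
      flux_residual = flux_resid,
      womersley = womersley_number(h, fluid,
                                   max(waveform$components$frequency)),
      n_points = n, steps_per_period = as.integer(steps_per_period),
      n_periods = as.integer(n_periods))
  )
}
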