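#' Two-harmonic physiological micromotion waveform
#'
#' Convenience constructor for a respiratory + cardiac electrode motion.
#' The respiratory component (15 um at 0.5 Hz) matches the motion used by
#' the flow models; the cardiac component defaults (3 um at 5 Hz) are
#' synthetic placeholders chosen to be small and fast relative to
#' respiration, since no measured cardiac amplitude is part of the model
#' inputs. They exist for generating richer synthetic traces only.
#'
#' @param resp_amplitude,resp_frequency respiratory component (m, Hz).
#' @param cardiac_amplitude,cardiac_frequency cardiac component (m, Hz);
#'   set `cardiac_amplitude = NULL` to omit it.
#' @return a [micromotion_waveform()].
#' @export
respiratory_cardiac_waveform <- function(resp_amplitude = 15e-6,
                                         resp_frequency = 0.5,
                                         cardiac_amplitude = 3e-6,
                                         cardiac_frequency = 5) {
  if (is.null(cardiac_amplitude)) {
    return(micromotion_waveform(resp_amplitude, resp_frequency))
  }
  micromotion_waveform(
    amplitude = c(resp_amplitude, cardiac_amplitude),
    frequency = c(resp_frequency, cardiac_frequency)
  )
}

#' Generate a sampled (optionally noisy) micromotion trace
#'
#' Samples the displacement of a micromotion waveform on a uniform time
#' grid and adds zero-mean Gaussian measurement noise. Fully seeded: the
#' same seed and arguments give bit-identical output.
#'
#' @param waveform a [micromotion_waveform()].
#' @param n_samples number of samples (>= 2).
#' @param duration trace duration (s); default one fundamental period.
#' @param noise_sd displacement noise standard deviation (m), >= 0.
#' @param seed integer seed.
#' @return tibble with `time` (s) and `displacement` (m).
#' @export
gen_micromotion <- function(waveform = micromotion_waveform(),
                            n_samples = 1000L, duration = NULL,
                            noise_sd = 0, seed = 1L) {
  check_waveform(waveform)
  if (n_samples < 2L) abort_invalid("`n_samples` must be >= 2.")
  if (is.null(duration)) duration <- waveform$period
  check_positive_scalar(duration, "duration")
  check_nonneg_scalar(noise_sd, "noise_sd")
  time <- seq(0, duration, length.out = n_samples + 1L)[seq_len(n_samples)]
  x <- displacement(waveform, time)
  if (noise_sd > 0) {
    x <- x + withr::with_seed(seed, stats::rnorm(n_samples, sd = noise_sd))
  }
  tibble(time = time, displacement = x)
}

#' Generate a noisy wall-shear observation trace with known ground truth
#'
#' Forward-simulates the tissue-wall shear of the quasi-steady gap-flow
#' model and perturbs it with multiplicative Gaussian noise,
#' \eqn{\tau_{obs} = \tau_{model} (1 + \epsilon)},
#' \eqn{\epsilon \sim N(0, \sigma_{rel}^2)}. Relative noise is used because
#' shear magnitudes span four orders of magnitude across the physiological
#' gap/viscosity ranges. The generating parameters are stored as the trace's
#' `truth` attribute for recovery scoring.
#'
#' @param gap a [gap_geometry()].
#' @param fluid a [fluid_properties()].
#' @param waveform a [micromotion_waveform()].
#' @param n_samples samples over `duration` (>= 2).
#' @param noise_rel_sd relative noise standard deviation, >= 0.
#' @param duration trace duration (s); default one fundamental period.
#' @param seed integer seed.
#' @return a `wss_trace` tibble (`time` s, `tau_obs` Pa) with attributes
#'   `truth` (list: `gap`, `viscosity`, `waveform`, `end_condition`,
#'   `noise_rel_sd`) and `seed`.
#' @export
gen_wss_observations <- function(gap, fluid,
                                 waveform = micromotion_waveform(),
                                 n_samples = 1000L, noise_rel_sd = 0.05,
                                 duration = NULL, seed = 1L) {
  check_gap(gap)
  check_fluid(fluid)
  check_waveform(waveform)
  if (n_samples < 2L) abort_invalid("`n_samples` must be >= 2.")
  check_nonneg_scalar(noise_rel_sd, "noise_rel_sd")
  if (is.null(duration)) duration <- waveform$period
  check_positive_scalar(duration, "duration")
  time <- seq(0, duration, length.out = n_samples + 1L)[seq_len(n_samples)]
  tau_model <- couette_wss(gap, fluid, velocity(waveform, time))$tau_tissue
  eps <- if (noise_rel_sd > 0) {
    withr::with_seed(seed, stats::rnorm(n_samples, sd = noise_rel_sd))
  } else {
    numeric(n_samples)
  }
  out <- tibble(time = time, tau_obs = tau_model * (1 + eps))
  attr(out, "truth") <- list(
    gap = gap$side_gap, viscosity = fluid$dynamic_viscosity,
    waveform = waveform, end_condition = gap$end_condition,
    noise_rel_sd = noise_rel_sd)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("wss_trace", class(out))
  out
}

# sign-carrying Couette factor: tau_tissue = k_end * mu * U / h
end_factor <- function(end_condition) {
  if (identical(end_condition, "open")) 1 else -2
}

new_wss_fit <- function(parameter, estimate, se, n_used, sigma_rel, truth) {
  structure(
    list(parameter = parameter, estimate = estimate, se = se,
         n_used = n_used, sigma_rel = sigma_rel, truth = truth),
    class = "wss_fit"
  )
}

check_trace <- function(trace) {
  if (!inherits(trace, "wss_trace")) {
    abort_invalid("`trace` must come from gen_wss_observations().")
  }
  if (!all(is.finite(trace$tau_obs)) || all(trace$tau_obs == 0)) {
    abort("trace is all-zero or non-finite; nothing to estimate.",
          class = "perimotion_estimation_failure")
  }
  invisible(trace)
}

# weighted least squares of tau_obs on the single-parameter forward model.
# Under multiplicative noise, weights 1/tau_model^2 make the per-sample
# ratios r_t i.i.d., so the WLS solution is their mean and the standard
# error follows from the fit curvature (= n / ratio variance).
ratio_fit <- function(trace, c_t) {
  keep <- abs(c_t) > 1e-9 * max(abs(c_t))
  r <- trace$tau_obs[keep] / c_t[keep]
  n <- length(r)
  theta <- mean(r)
  if (!is.finite(theta) || theta <= 0) {
    abort("estimation failed: non-positive parameter ratio.",
          class = "perimotion_estimation_failure")
  }
  se_theta <- if (n > 1) stats::sd(r) / sqrt(n) else 0
  list(theta = theta, se_theta = se_theta, n = n,
       sigma_rel = if (n > 1) stats::sd(r) / theta else 0)
}

#' Recover the gap or the viscosity from a noisy shear trace
#'
#' Single-parameter weighted least-squares inversion of the quasi-steady
#' forward model \eqn{\tau(t) = k\,\mu\,U(t)/h} (k = -2 for a closed
#' cavity, 1 for open ends). `recover_gap()` treats the viscosity and
#' waveform as known and estimates the gap `h`; `recover_viscosity()` is
#' the mirror image. Joint recovery of both is refused: the model depends
#' on them only through the ratio \eqn{\mu/h}, so they are not jointly
#' identifiable from a shear trace.
#'
#' @param trace a `wss_trace` from [gen_wss_observations()].
#' @param fluid the known [fluid_properties()] (for `recover_gap()`).
#' @param waveform the known [micromotion_waveform()].
#' @param gap the known gap: a [gap_geometry()] or a per-side distance in
#'   metres (for `recover_viscosity()`).
#' @return A `wss_fit` object with elements `parameter`, `estimate`, `se`,
#'   `n_used`, `sigma_rel`; see [tidy.wss_fit()] and [glance.wss_fit()].
#' @examples
#' tr <- gen_wss_observations(gap_geometry(50e-6), interstitial_fluid(50e-3),
#'                            noise_rel_sd = 0.05, seed = 7)
#' tidy(recover_gap(tr, interstitial_fluid(50e-3), micromotion_waveform()))
#' @export
recover_gap <- function(trace, fluid, waveform = micromotion_waveform()) {
  check_trace(trace)
  check_fluid(fluid)
  check_waveform(waveform)
  truth <- attr(trace, "truth")
  k_end <- end_factor(truth$end_condition)
  # tau = (k mu U) / h: linear in theta = 1/h
  c_t <- k_end * fluid$dynamic_viscosity * velocity(waveform, trace$time)
  fit <- ratio_fit(trace, c_t)
  est <- 1 / fit$theta
  new_wss_fit("gap", est, fit$se_theta / fit$theta^2, fit$n, fit$sigma_rel,
              truth$gap)
}

#' @rdname recover_gap
#' @export
recover_viscosity <- function(trace, gap,
                              waveform = micromotion_waveform()) {
  check_trace(trace)
  if (inherits(gap, "gap_geometry")) gap <- gap$side_gap
  check_positive_scalar(gap, "gap")
  check_waveform(waveform)
  truth <- attr(trace, "truth")
  k_end <- end_factor(truth$end_condition)
  # tau = (k U / h) mu: linear in mu
  c_t <- k_end * velocity(waveform, trace$time) / gap
  fit <- ratio_fit(trace, c_t)
  new_wss_fit("viscosity", fit$theta, fit$se_theta, fit$n, fit$sigma_rel,
              truth$viscosity)
}

#' @rdname recover_gap
#' @param which character vector naming the parameter(s) to estimate,
#'   among `"gap"` and `"viscosity"`. Requesting both raises an
#'   identifiability error.
#' @param ... passed to the single-parameter estimator.
#' @export
recover_wss_parameters <- function(trace, which, ...) {
  which <- match.arg(which, c("gap", "viscosity"), several.ok = TRUE)
  if (length(unique(which)) > 1L) {
    abort(
      paste0("joint recovery of gap and viscosity is not identifiable: the ",
             "quasi-steady shear depends on them only through mu/h. Fix one ",
             "and estimate the other."),
      class = "perimotion_nonidentifiable"
    )
  }
  switch(unique(which),
         gap = recover_gap(trace, ...),
         viscosity = recover_viscosity(trace, ...))
}

#' @export
print.wss_fit <- function(x, ...) {
  cat(sprintf("<wss_fit> %s = %.6g (se %.3g), n = %d\n",
              x$parameter, x$estimate, x$se, x$n_used))
  invisible(x)
}

#' Tidy and glance methods for shear-trace fits
#'
#' @param x a `wss_fit` from [recover_gap()] or [recover_viscosity()].
#' @param ... unused.
#' @return `tidy()`: a tibble with `term`, `estimate`, `std.error`;
#'   `glance()`: a one-row tibble with `nobs`, `sigma_rel` (relative
#'   residual SD) and, when ground truth is stored, `truth` and
#'   `rel_error`.
#' @method tidy wss_fit
#' @export
tidy.wss_fit <- function(x, ...) {
  tibble(term = x$parameter, estimate = x$estimate, std.error = x$se)
}

#' @rdname tidy.wss_fit
#' @method glance wss_fit
#' @export
glance.wss_fit <- function(x, ...) {
  tibble(
    nobs = x$n_used,
    sigma_rel = x$sigma_rel,
    truth = x$truth %||% NA_real_,
    rel_error = if (!is.null(x$truth)) {
      abs(x$estimate - x$truth) / x$truth
    } else {
      NA_real_
    }
  )
}
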