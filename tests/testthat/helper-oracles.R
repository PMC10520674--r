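# Independent oracles and shared fixtures, kept deliberately separate from
# the package implementation.

# Exact solution of the finite-gap oscillatory Stokes problem with open
# ends (no pressure gradient): u(y,t) = Re[ U_hat sinh(lambda y) /
# sinh(lambda h) e^{i omega t} ], lambda = sqrt(i omega / nu), driven by a
# single sinusoidal displacement A sin(omega t) so the wall speed is
# U(t) = A omega cos(omega t) = Re[ A omega e^{i omega t} ].
exact_stokes_tau_tissue <- function(h, mu, rho, times, A = 15e-6, f = 0.5) {
  omega <- 2 * pi * f
  nu <- mu / rho
  lambda <- sqrt(1i * omega / nu)
  u_hat <- A * omega
  Re(mu * u_hat * lambda / sinh(lambda * h) * exp(1i * omega * times))
}

exact_stokes_peak <- function(h, mu, rho, A = 15e-6, f = 0.5) {
  omega <- 2 * pi * f
  nu <- mu / rho
  lambda <- sqrt(1i * omega / nu)
  Mod(mu * A * omega * lambda / sinh(lambda * h))
}

# viscosity that yields a prescribed Womersley number alpha = h sqrt(omega
# rho / mu) for the default 0.5 Hz drive
viscosity_for_alpha <- function(alpha, h, rho = 1006, f = 0.5) {
  2 * pi * f * rho * h^2 / alpha^2
}

# shared fixtures: the mid-range benchmark condition
bench_gap <- function() gap_geometry(side_gap = 50e-6)
bench_fluid <- function() interstitial_fluid(50e-3)
bench_peak_speed <- 2 * pi * 0.5 * 15e-6    # 4.712389e-05 m/s
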