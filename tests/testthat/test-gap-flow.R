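test_that("quasi-steady Couette wall stresses match the closed forms", {
  gp <- bench_gap()
  fl <- bench_fluid()
  u <- bench_peak_speed
  tau <- couette_wss(gp, fl, u)
  # sealed cavity: 2 mu U / h at the tissue, 4 mu U / h at the electrode
  expect_equal(abs(tau$tau_tissue), 2 * 50e-3 * u / 50e-6)
  expect_equal(abs(tau$tau_tissue), 0.0942, tolerance = 1e-3)
  expect_equal(abs(tau$tau_electrode), 2 * abs(tau$tau_tissue))
  # open ends: plain Couette mu U / h on both walls, half the closed value
  gp_open <- gap_geometry(50e-6, end_condition = "open")
  tau_o <- couette_wss(gp_open, fl, u)
  expect_equal(tau_o$tau_tissue, tau_o$tau_electrode)
  expect_equal(abs(tau_o$tau_tissue), abs(tau$tau_tissue) / 2)
  expect_equal(abs(tau_o$tau_tissue), 0.0471, tolerance = 2e-3)
  # zero speed, sign-flip with wall speed
  expect_equal(unlist(couette_wss(gp, fl, 0)), c(tau_tissue = 0, tau_electrode = 0))
  tau_neg <- couette_wss(gp, fl, -u)
  expect_equal(tau_neg$tau_tissue, -tau$tau_tissue)
  expect_equal(tau_neg$tau_electrode, -tau$tau_electrode)
})

test_that("analytic series reproduces benchmark peak and cycle average", {
  s <- wss_timeseries(bench_gap(), bench_fluid())
  expect_equal(wss_peak(s), 2 * 50e-3 * bench_peak_speed / 50e-6)
  expect_equal(wss_peak(s), 0.0942, tolerance = 1e-3)
  expect_equal(wss_cycle_avg(s), wss_peak(s) * 2 / pi, tolerance = 1e-4)
  expect_equal(wss_cycle_avg(s), 0.0600, tolerance = 1e-3)
  # low-shear corner of the physiological range
  s2 <- wss_timeseries(gap_geometry(150e-6), interstitial_fluid(1.2e-3))
  expect_equal(wss_cycle_avg(s2), 4.80e-4, tolerance = 1e-3)
  # signed mean vanishes over a full period (odd symmetry)
  expect_lt(abs(mean(s$tau_tissue)) / wss_peak(s), 1e-12)
  expect_gte(wss_peak(s), wss_cycle_avg(s))
})

test_that("peak and cycle-average summaries are phase invariant", {
  set.seed(11)
  base <- wss_timeseries(bench_gap(), bench_fluid(),
                         micromotion_waveform(phase = 0))
  for (phi in runif(5, -pi, pi)) {
    s <- wss_timeseries(bench_gap(), bench_fluid(),
                        micromotion_waveform(phase = phi))
    expect_equal(wss_peak(s), wss_peak(base), tolerance = 1e-4)
    expect_equal(wss_cycle_avg(s), wss_cycle_avg(base), tolerance = 1e-4)
  }
})

test_that("analytic shear obeys exact power-law scalings", {
  set.seed(22)
  for (i in 1:10) {
    h <- runif(1, 10e-6, 150e-6)
    mu <- runif(1, 1.2e-3, 100e-3)
    u <- runif(1, 1e-6, 1e-4)
    tau <- abs(couette_wss(gap_geometry(h), fluid_properties(1006, mu), u)$tau_tissue)
    # tau ~ mu, tau ~ U, tau ~ 1/h
    expect_equal(abs(couette_wss(gap_geometry(h), fluid_properties(1006, 3 * mu), u)$tau_tissue),
                 3 * tau)
    expect_equal(abs(couette_wss(gap_geometry(h), fluid_properties(1006, mu), 5 * u)$tau_tissue),
                 5 * tau)
    expect_equal(abs(couette_wss(gap_geometry(2 * h), fluid_properties(1006, mu), u)$tau_tissue),
                 tau / 2)
  }
})

test_that("squeeze-film shear follows lubrication theory", {
  wf <- micromotion_waveform()       # 15 um normal motion at 0.5 Hz
  fl <- bench_fluid()
  # rim stress at the instant of peak approach speed (t = 0, g = 100 um)
  tau <- squeeze_film_wss(50e-6, 100e-6, wf, fl, r = 50e-6, t = 0)
  expect_equal(tau, 3 * 50e-3 * 50e-6 * bench_peak_speed / (100e-6)^2)
  expect_equal(tau, 0.0353, tolerance = 2e-3)
  # zero on the axis, zero without motion, maximal at the rim
  expect_equal(squeeze_film_wss(50e-6, 100e-6, wf, fl, 0, runif(4)),
               rep(0, 4))
  still <- micromotion_waveform(amplitude = 0)
  expect_equal(squeeze_film_wss(50e-6, 100e-6, still, fl,
                                rep(25e-6, 3), c(0, 0.3, 1)), rep(0, 3))
  r <- seq(0, 50e-6, length.out = 11)
  tau_r <- squeeze_film_wss(50e-6, 100e-6, wf, fl, r, rep(0.2, 11))
  expect_true(all(diff(tau_r) > 0))
  # linear in r: consistent with radial volume conservation under the disc
  expect_equal(tau_r[11], 2 * tau_r[6], tolerance = 1e-12)
  # contact refusal when the stroke reaches the film thickness
  expect_error(squeeze_film_wss(50e-6, 10e-6, wf, fl, 25e-6, 0),
               class = "perimotion_contact_singularity")
})

test_that("tissue mechanical constants change no flow output", {
  wf <- micromotion_waveform()
  base <- wss_timeseries(bench_gap(), bench_fluid(), wf)
  soft <- tissue_properties(density = 900, youngs_modulus = 1e3,
                            poisson_ratio = 0.3)
  stiff <- tissue_properties(density = 1200, youngs_modulus = 50e3,
                             poisson_ratio = 0.49)
  for (tp in list(soft, stiff)) {
    alt <- wss_timeseries(bench_gap(), bench_fluid(), wf, tissue = tp)
    expect_identical(alt$tau_tissue, base$tau_tissue)
    expect_identical(alt$tau_electrode, base$tau_electrode)
  }
  fd_base <- fd_gap_solver(bench_gap(), bench_fluid(), wf, n_points = 51)
  fd_alt <- fd_gap_solver(bench_gap(), bench_fluid(), wf, n_points = 51,
                          tissue = stiff)
  expect_identical(fd_alt$tau_tissue, fd_base$tau_tissue)
})

test_that("geometry and regime guards fire", {
  expect_error(gap_geometry(side_gap = 0),
               class = "perimotion_invalid_parameter")
  expect_error(wss_timeseries(bench_gap(), bench_fluid(),
                              samples_per_period = 32),
               class = "perimotion_invalid_parameter")
  # outside the quasi-steady regime the analytic model warns
  thin <- fluid_properties(1006, viscosity_for_alpha(2, 150e-6))
  expect_warning(wss_timeseries(gap_geometry(150e-6), thin),
                 class = "perimotion_unsteady_warning")
})
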