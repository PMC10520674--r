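# perimotion

Shear-stress dosimetry of neuroelectrode micromotion.

Chronically implanted neural probes (stimulation and recording electrodes)
move relative to the brain with respiration and pulse — tens of
micrometres at around 0.5 Hz. Around a chronic implant the tissue recedes,
leaving a fluid-filled peri-electrode void, and electrode motion inside
that void drives an oscillatory flow whose wall shear stress (WSS) on the
peri-electrode tissue is a candidate mechanical driver of reactive
gliosis and neuronal loss. `perimotion` is for neuroengineers and
mechanobiologists who need those stresses quantified: it computes the
micromotion-induced WSS across the physiological ranges of gap and
interstitial-fluid viscosity, calibrates the parallel-plate flow-chamber
(PPFC) flow rates that reproduce a chosen WSS on cultured cells, and
simulates the expansion of the void to a steady state set by a WSS
threshold.

## The models

**Gap flow.** The void is a sealed plane channel of per-side width $h$;
the electrode wall moves with $U(t) = 2\pi f A\cos(2\pi f t)$
($A = 15\ \mu$m, $f = 0.5$ Hz by default) and the end walls force the net
cross-gap flux to zero, so the quasi-steady tissue-wall stress is

$$\tau_{\mathrm{tissue}} = \frac{2\mu U(t)}{h}$$

(in magnitude; $4\mu U/h$ on the electrode wall, $\mu U/h$ for open
ends). Validity is controlled by the Womersley number
$\alpha = h\sqrt{2\pi f\rho/\mu}$, and an unsteady Crank–Nicolson
finite-difference Stokes solver (`fd_gap_solver()`) covers the regime
where the quasi-steady model breaks down. A lubrication squeeze-film term
(`squeeze_film_wss()`) models the electrode tip face.

**PPFC dosimetry.** For a wide shallow channel of width $b$ and height
$h$, $\tau_w = 6Q\mu/(bh^2)$; `solve_channel()` recovers $(b, h)$ from
the aspect ratio $b/h = 120$ and a calibration point, and
`reynolds_channel()` / `homogeneity_report()` check that a condition is
laminar and quasi-steady.

**Void dynamics.** While the WSS at the tissue wall exceeds a threshold
$\tau_c$ (default 0.1 Pa) the gap grows, $dg/dt = k(\tau(g)-\tau_c)_+$,
reaching the fixed point $g^\ast = 2\mu U_{\mathrm{peak}}/\tau_c$.

**Synthetic data.** Seeded generators produce micromotion traces and
noisy WSS observations with known ground truth; `recover_gap()` /
`recover_viscosity()` invert the forward model by weighted least squares
(with broom-style `tidy()`/`glance()` methods), and joint recovery of
$(\mu, h)$ is refused as structurally non-identifiable.

See the methods vignette (`vignettes/perimotion-methods.Rmd`) for
derivations, numerical choices and limitations.

## Worked example

```r
library(perimotion)

# micromotion-induced WSS at the mid-range condition:
# 50 um per-side gap, 50 mPa s interstitial fluid
s <- wss_timeseries(gap_geometry(side_gap = 50e-6), interstitial_fluid(50e-3))
s
#> <wss_series> solver = analytic, peak |tau| = 0.09425 Pa, cycle-avg |tau| = 0.06 Pa
```

The peak tissue-wall stress is 0.094 Pa — the ~0.1 Pa dose at which
astrocyte reactivity is studied in vitro — and the cycle-averaged
magnitude is $2/\pi$ of it.

```r
# chamber that delivers 0.1 Pa at 4.49 mL/min, and the 0.5 Pa flow rate
ch <- solve_channel()
ch
#> <ppfc_channel> b = 39.18 mm, h = 326.5 um, b/h = 120
m3s_to_ml_min(flow_for_wss(0.5, culture_medium(), ch))
#> [1] 22.45
homogeneity_report(ppfc_condition(ml_min_to_m3s(4.49), culture_medium(), ch))
#> # A tibble: 1 × 4
#>   womersley reynolds quasi_steady laminar
#>       <dbl>    <dbl> <lgl>        <lgl>
#> 1     0.301     2.07 TRUE         TRUE
```

The chamber height and width follow from the aspect ratio and the
calibration point; delivering 0.5 Pa needs exactly 5× the flow
(22.45 mL/min), and at the 0.1 Pa condition the flow is laminar
(Re = 2.07) and quasi-steady (half-height Womersley number 0.30).

```r
# void expansion to the steady state set by the 0.1 Pa threshold
tr <- simulate_expansion(void_params(rate_k = 1e-9, initial_gap = 10e-6))
tr
#> <void_trajectory> terminal gap = 47.12 um, void diameter = 194.2 um, converged: TRUE

# recover the gap from a noisy synthetic shear trace
o <- gen_wss_observations(gap_geometry(50e-6), interstitial_fluid(50e-3),
                          noise_rel_sd = 0.05, seed = 7)
tidy(recover_gap(o, interstitial_fluid(50e-3), micromotion_waveform()))
#> # A tibble: 1 × 3
#>   term   estimate    std.error
#>   <chr>     <dbl>        <dbl>
#> 1 gap   0.0000500 0.0000000775
```

The void stabilises where the stress falls to the threshold: a 47 µm
per-side gap, i.e. a 194 µm void around the 100 µm electrode (1.9×
its diameter). The estimator recovers the true 50 µm gap from a 5%-noise
trace with a sub-permille standard error.

Each result type has an `autoplot()` method (shear series, sweep heatmap,
expansion trajectory), and `run_sweep()` maps both WSS metrics over the
gap × viscosity grid as a tidy tibble. A thin CLI wrapper is installed at
`inst/cli/perimotion` (subcommands `gapflow`, `ppfc`, `void`, `sweep`,
`synth`, `recover`).

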