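---
title: "Models and methods: micromotion shear dosimetry at the electrode-tissue interface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: micromotion shear dosimetry at the electrode-tissue interface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perimotion)
```

## The problem

Chronically implanted neural probes do not sit still: respiration and the
cardiac cycle move the brain relative to the implant by tens of micrometres
at sub-hertz to few-hertz rates. Around a chronic implant the tissue
recedes, leaving a fluid-filled peri-electrode void. Electrode motion
inside that void drives an oscillatory flow of interstitial fluid, and the
wall shear stress (WSS) this flow exerts on the surrounding tissue is a
candidate mechanical trigger for astrocyte reactivity and neuronal loss.
`perimotion` provides reduced-order, fully tested models of this chain:
the gap flow and its WSS, the flow-chamber dosimetry used to apply matched
WSS to cultured cells, and a minimal dynamic model of void expansion to a
steady state set by a WSS threshold.

The study conditions baked into the defaults are: a 100 µm diameter
electrode; respiration-driven motion of amplitude $A = 15$ µm (30 µm
peak-to-peak) at $f = 0.5$ Hz; interstitial fluid of density
$\rho = 1006$ kg m$^{-3}$ and dynamic viscosity $\mu$ between 1.2 and
100 mPa s (healthy to pathological); and, for the in-vitro arm, culture
medium of density 1009 kg m$^{-3}$ and viscosity 0.930 mPa s.

## Gap flow: quasi-steady Couette model with zero net flux

The peri-electrode void is modelled as a plane channel of width $h$ (the
per-side electrode-tissue distance) bounded by the moving electrode wall,
with speed $U(t) = 2\pi f A \cos(2\pi f t)$, and the stationary tissue
wall. Whether the quasi-steady approximation applies is governed by the
Womersley number

$$\alpha = h \sqrt{\frac{2\pi f \rho}{\mu}},$$

the ratio of oscillatory inertia to viscous diffusion. At the benchmark
condition ($h = 50$ µm, $\mu = 50$ mPa s) $\alpha = 0.0126$, so the
velocity profile relaxes essentially instantaneously and the flow is a
sequence of steady states. (Convention: the full gap is the characteristic
length here; for the flow chamber below the half-height is used. The
`char_length` argument of `womersley_number()` leaves the choice to the
caller.)

Because the void is a sealed cavity, the end walls force the net
cross-gap flux to zero: the linear Couette profile acquires a
pressure-driven backflow. Writing
$u(y) = U y/h + \frac{G}{2\mu}(y^2 - yh)$ and imposing
$\int_0^h u\,dy = 0$ gives $G = 6\mu U/h^2$ and wall gradients

$$\tau_{\text{tissue}} = -\frac{2\mu U}{h}, \qquad
  \tau_{\text{electrode}} = +\frac{4\mu U}{h},$$

i.e. double (tissue) and quadruple (electrode) the open-ended Couette
value $\mu U/h$. The closed-end condition is the default: a sealed void is
the physically relevant geometry, and it is the configuration whose
tissue-wall stress reproduces the ~0.1 Pa benchmark at the mid-range
condition (the open-end value is half that). Reported stresses are
$\mu\,\partial u/\partial y$ at the wall, so signs flip with the direction
of motion; all summary metrics use magnitudes.

Two summary metrics are always reported, because "average WSS" is
ambiguous for an oscillatory signal: the peak magnitude over a cycle and
the cycle-averaged magnitude. For a pure sinusoid their ratio is exactly
$2/\pi$. At the benchmark condition the peak is
$2\mu\,(2\pi f A)/h = 0.0942$ Pa and the cycle average 0.060 Pa.

### The finite-difference solver

`fd_gap_solver()` drops the quasi-steady assumption and integrates the
unsteady Stokes problem

$$\frac{\partial u}{\partial t}
  = \nu \frac{\partial^2 u}{\partial y^2} - \frac{G(t)}{\rho}$$

with $u(0,t)=0$, $u(h,t)=U(t)$, and, for closed ends, $G(t)$ determined
at every step so that the discrete flux $\int_0^h u\,dy$ vanishes exactly.
The flow is laminar by construction: the gap Reynolds number
$U h/\nu$ is far below unity across the whole physiological range, so a
turbulence closure has no physical role here.

Numerical choices:

* **Crank–Nicolson** time stepping ($\theta = 1/2$), second order and
  unconditionally stable. The constant tridiagonal matrix is factorised
  once (Thomas algorithm) and reused.
* The flux constraint is enforced by **linear superposition**: each step
  solves one system for the known right-hand side and combines it with a
  precomputed unit-pressure response so that the trapezoidal flux is zero
  to rounding. The largest flux residual over all steps is returned as an
  attribute and is of order $10^{-16}$ relative.
* Wall stress uses a **one-sided second-order stencil**
  $\mu(4u_2 - u_3)/(2\Delta y)$, so the stress converges at the same
  order as the field. Under joint refinement of $\Delta y$ and $\Delta t$
  the error against the exact oscillatory solution decays at second
  order.
* The run starts from the quasi-steady profile at $t=0$ and the first
  $n_{\text{periods}}-1$ periods are discarded; the slowest diffusive
  transient decays by $e^{-2\pi^3/\alpha^2}$ per period, so even at
  $\alpha = 5$ a handful of discarded periods suffices.
* Defaults (201 grid points, 400 steps per period, 5 periods) resolve the
  benchmark peak to about 0.01%; the test suite uses 101 points where many
  solves are needed.

The solver is verified two ways: against the quasi-steady analytic model
for randomized $(h,\mu)$ pairs with $\alpha < 0.1$, and against the exact
complex-exponential solution of the finite-gap oscillatory Stokes problem
(open ends, $u \propto \sinh(\lambda y)/\sinh(\lambda h)$,
$\lambda = \sqrt{i\omega/\nu}$) at $\alpha = 5$, far outside the
quasi-steady regime. The exact solution is implemented independently in
the test helpers, not in the package, so the two routes cannot collapse
into one.

### Tip squeeze film

The stepped tip of a real probe also displaces fluid normal to its end
face. `squeeze_film_wss()` provides the standard lubrication result for a
rigid disc of radius $R$ approaching a plane across a film $g(t)$:
$\tau(r,t) = 3\mu r |\dot g|/g^2$, zero on the axis, maximal at the rim,
and refusing to run if the stroke reaches the film thickness. This term is
deliberately *not* folded into the plane-gap sweep: it is the documented
mechanism by which tip-region stresses can exceed the tangential-gap
prediction, but its geometry (tip gap, averaging surface) is not
constrained by the available inputs, and tuning it to close the gap with
any particular reported figure would be curve fitting, not modelling.

### Rigid tissue

Brain tissue constants (density 1060 kg m$^{-3}$, Young's modulus 6 kPa,
Poisson's ratio 0.45) are recorded by `tissue_properties()` for
configuration completeness, but the tissue wall is rigid in every flow
model; a test asserts bit-identical output under arbitrary changes of
these constants. Fluid–structure interaction is a known limitation, noted
below.

## Flow-chamber dosimetry

The in-vitro arm delivers a prescribed WSS to a cell monolayer with a
parallel-plate flow chamber (PPFC). For a wide, shallow channel
(width $b$, height $h$) in laminar plane-Poiseuille flow,

$$\tau_w = \frac{6 Q \mu}{b h^2}.$$

The chamber is specified by its aspect ratio $b/h = 120$ and one
calibration point — 4.49 mL min$^{-1}$ of culture medium yields 0.1 Pa —
rather than by raw dimensions. `solve_channel()` closes the system:
$h = (6Q\mu / (\tau\,b/h))^{1/3} = 326.6$ µm and $b = 39.19$ mm
(consistent with a standard 38 mm slide). Dose–flow linearity is exact,
so the 0.5 Pa arm needs exactly $5\times$ the flow (22.45 mL min$^{-1}$)
and a 1 Pa arm 44.9 mL min$^{-1}$.

Two regime checks accompany the dose:

* **Reynolds number.** Convention: characteristic length = channel
  height, $Re = \rho Q/(\mu b)$, giving 2.07 at the 0.1 Pa condition.
  This is an inference — with the hydraulic-diameter convention
  ($D_h \approx 2h$) the same condition gives about 4.1 — and it is the
  convention under which the condition sits below the quoted bound of
  2.4; it is documented as such in `reynolds_channel()`. Either way the
  flow is deeply laminar (transition in a plane channel is of order
  $Re \sim 1400$).
* **Womersley number** on the half-height: $\alpha = 0.30$ at 0.5 Hz, so
  the oscillatory drive modulates the parabolic profile quasi-statically
  and the wall shear simply follows the instantaneous flow rate. No
  entrance-region modelling is attempted.

## Void expansion to a steady state

The dynamic hypothesis is minimal: while the micromotion-induced WSS at
the tissue wall exceeds a reactivity threshold $\tau_c$ (default 0.1 Pa),
tissue recedes and the per-side gap grows,

$$\frac{dg}{dt} = k \,\max\!\big(0,\ \tau(g) - \tau_c\big),
\qquad \tau(g) = \frac{2\mu S}{g},$$

with $S$ the peak (default) or cycle-averaged wall speed. Only the fixed
point is treated as physically grounded:

$$g^* = \frac{2\mu S}{\tau_c},$$

the gap at which shear falls to the threshold. The rate constant $k$ is
explicitly non-identifiable from steady-state observations; it sets the
relaxation time $g^*/(k\tau_c)$ and nothing else, which the tests assert
by varying $k$ over two decades. Integration is explicit Euler with
step-halving acceptance on the gap increment — entirely adequate for a
monotone scalar ODE — with the default horizon at 30 relaxation times so
the terminal stress sits within $10^{-6}$ of the threshold.

At the default conditions ($\mu = 50$ mPa s, peak metric,
$\tau_c = 0.1$ Pa) the model predicts $g^* = 47.1$ µm per side, i.e. a
void diameter of 194 µm — about $1.9\times$ the electrode diameter.
Chronic peri-implant voids are observed at roughly 2–4 electrode
diameters, so the minimal model lands at, or just below, the lower edge
of that envelope. The package does not assert agreement; instead it
exposes the three knobs the discrepancy is sensitive to — the metric
(cycle-average lowers $g^*$ by $2/\pi$), the threshold (a lower effective
$\tau_c$ raises $g^*$ proportionally), and the neglected tip squeeze-film
contribution (which raises near-tip stress and hence the steady gap).
Whether the in-vivo multiple reflects one of these or a biological rate
process is not decidable from the modelled physics alone.

## Synthetic data and parameter recovery

`gen_micromotion()` and `gen_wss_observations()` generate seeded,
bit-reproducible traces: a sum of harmonics (respiratory, optionally
cardiac) with optional additive displacement noise, and the quasi-steady
forward-model shear with *multiplicative* Gaussian noise
$\tau_{\text{obs}} = \tau(1+\varepsilon)$,
$\varepsilon \sim N(0, \sigma_{\text{rel}}^2)$. Relative noise is the
right error model here because shear magnitudes span four orders of
magnitude across the gap/viscosity ranges. The cardiac defaults (3 µm at
5 Hz) are synthetic placeholders — small and fast relative to respiration
— and appear only in this module; no measured cardiac amplitude is among
the model inputs.

Recovery is single-parameter weighted least squares against the forward
model $\tau(t) = k_{\text{end}}\,\mu\,U(t)/h$. With weights
$1/\tau_{\text{model}}^2$ the per-sample ratios
$r_t = \tau_{\text{obs}}/(k_{\text{end}}\mu U(t))$ are i.i.d., the WLS
estimate is their mean, and the standard error follows from the fit
curvature; samples within $10^{-9}$ of a zero crossing of $U$ are
excluded (the multiplicative noise model carries no information there).
Noiseless recovery is exact to $10^{-9}$ relative; at 5% noise and
$n = 1000$ the error is well under 10% and the root-mean-square error
contracts as $1/\sqrt{n}$.

Joint recovery of $(\mu, h)$ is *refused*, not worked around: the
quasi-steady shear depends on them only through $\mu/h$, so the pair is
structurally non-identifiable, and `recover_wss_parameters()` raises a
classed error saying so.

What the generator does **not** emulate: aperiodic motion (movement
artefacts), non-Newtonian or spatially heterogeneous interstitial fluid,
measurement drift, or correlated noise. Passing recovery tests therefore
demonstrate estimator correctness under the stated error model, not
robustness to real instrumentation.

## Sweeps, configuration, interfaces

`run_sweep()` maps both WSS metrics over the default grid — 8 gaps linear
in 10–150 µm by 8 viscosities log-spaced in 1.2–100 mPa s — returning a
long-form tibble (one row per cell, both metrics as columns) rather than
a matrix, so results pipe directly into dplyr and `autoplot()`. Two exact
monotonicities are machine-checked on every sweep: WSS strictly falls
with gap at fixed viscosity and strictly rises with viscosity at fixed
gap.

Configuration is a single JSON document (sections `micromotion`, `fluid`,
`geometry`, `ppfc`, `void`, `sweep`, `synth`) in bench units; unknown
keys are rejected with the offending field path, missing keys fall back
to defaults, and a write/read round trip reproduces the defaults exactly.
A thin command-line wrapper (`inst/cli/perimotion`, subcommands
`gapflow`, `ppfc`, `void`, `sweep`, `synth`, `recover`) exposes the same
functions for shell use; logs go to standard error, results to CSV on
standard output or `--out`, and exit codes distinguish validation errors
(2) from solver failures (3).

## Problem sizes and tolerances

The test suite and the acceptance script use: 512 samples per period for
analytic series (2048 where the $2/\pi$ identity is checked to 0.5%);
101 grid points × 200 steps per period for the randomized FD-vs-analytic
equivalence (20 pairs, 1% tolerance) and 101 × 400 × 8 periods for the
$\alpha = 5$ exact-solution check; 40 replicates per sample size for the
$1/\sqrt{n}$ consistency check over $n \in \{10^2, 10^3, 10^4\}$; and 200
seeded replicates for the recovery-bias bound. These sizes were chosen so
each property is resolved an order of magnitude finer than the tolerance
it is tested at.

## Known limitations

* One-dimensional gap flow: the stepped 2-D tip geometry enters only
  through the optional squeeze-film term, so spatially averaged stresses
  over a real probe surface — particularly near the tip at small gaps and
  high viscosities — can exceed the plane-gap prediction severalfold.
* Rigid tissue wall; no poroelastic or fluid–structure coupling.
* Newtonian, homogeneous interstitial fluid.
* The void model's rate law is phenomenological; only its fixed point is
  intended to carry physical meaning.
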