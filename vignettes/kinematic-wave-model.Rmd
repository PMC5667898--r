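---
title: "The kinematic-wave model behind prpspin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The kinematic-wave model behind prpspin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prpspin)
```

# The physical model

## Hindered settling in a centrifugal field

A tube of whole blood is treated as a suspension of red blood cells (volume
fraction $\alpha$, the hematocrit initially) in plasma. A single particle of
diameter $d$ and density $\rho_p$ settles through plasma (density $\rho_f$,
viscosity $\mu$) at the Stokes velocity

$$u_\infty = \frac{(\rho_p - \rho_f)\, g\, d^2}{18 \mu},$$

which `stokes_settling_velocity()` evaluates (about $3.2\,\mu\mathrm{m/s}$
for an $8\,\mu$m red cell at $1\,g$). In a centrifuge the local acceleration
is $\omega^2 r$, so the settling velocity grows linearly with radius; the
particle Reynolds number stays far below unity for every protocol considered
here (`particle_reynolds()` warns otherwise), so Stokes drag remains valid.

At finite concentration the cells hinder each other. The package uses the
Richardson–Zaki closure: the suspension flux (volume of solids crossing unit
area per unit time, positive outward) is

$$f(\alpha) = -\,\alpha (1 - \alpha)^m \, u_\infty \frac{\omega^2 r}{g},$$

with exponent $m = 5$, cut off to zero outside $(0, \alpha_{\max})$ where
$\alpha_{\max} = 0.8$ is the packed-bed ("hematocrit of the sediment")
limit. `batch_flux()` evaluates the dimensionless part
$\tilde f(\alpha) = -\alpha(1-\alpha)^m$, which has a single interior
extremum at $\alpha = 1/(m+1)$.

## The Kynch conservation law

Conservation of solids along the tube axis (radial coordinate $r$, tube
bottom at the rotor radius $R_o$) gives the kinematic-wave equation. With
$r^* = r / R_o$ and the dimensionless time
$t^* = t\, \omega^2 u_\infty / g$,

$$\frac{\partial \alpha}{\partial t^*}
  + \frac{\partial}{\partial r^*}\bigl( r^* \tilde f(\alpha) \bigr) = 0 .$$

This is a scalar non-convex conservation law: solutions develop a clear
supernatant above a descending concentration front, a packed bed growing
from the bottom, and — for suitable parameters — a retarded-settling zone in
between. The radial factor $r^*$ makes the front accelerate as it moves
outward; while the suspension below the front stays spatially uniform it
dilutes along the characteristic ODE
$\mathrm{d}\alpha/\mathrm{d}t^* = -\alpha (1-\alpha)^m$, and the front obeys
the Rankine–Hugoniot speed of a shock against clear liquid. Both exact
results are used as oracles in the test suite.

# The numerical scheme

`solve_sedimentation()` integrates the conservation law with a first-order
explicit finite-volume method:

- the filled column (height from `tube_geometry()` and the blood volume) is
  divided into `n_cells` equal-height cells (default 200), cell 1 at the
  bottom; on conical-bottom tubes the update is area-weighted so solids are
  conserved exactly on the frustum;
- interior face fluxes use the monotone **Engquist–Osher (EO)** splitting
  $F(\alpha_L, \alpha_R) = g(0) + \int_0^{\alpha_L}\max(g',0)
  + \int_0^{\alpha_R}\min(g',0)$ with $g = r^*\tilde f$, evaluated in closed
  form because $\tilde f$ has one interior extremum; the upward jump of the
  clamped flux at $\alpha_{\max}$ is assigned to the increasing part.
  $\alpha_L$ is the cell nearer the bottom. For states on one monotone side
  of the extremum, and for all rarefaction configurations, EO coincides with
  the Godunov flux; for shocks straddling the extremum it is the more
  diffusive of the two monotone fluxes (by at most
  $|\tilde f(1/(m+1))| \approx 0.067$), which slightly widens the settling
  front but converges to the same entropy solution;
- time stepping is explicit Euler at the CFL limit
  $\Delta t^* = \mathrm{cfl} \cdot \Delta r^* / \max|\,(r^* \tilde f)'\,|$
  with `cfl = 0.5`;
- because the clamped flux drops discontinuously to zero at
  $\alpha_{\max}$, an explicit step can overshoot the packing limit by up to
  $\mathrm{cfl}\cdot|\tilde f(\alpha_{\max}^-)| \approx 1.3\times10^{-4}$;
  after each step any excess above $\alpha_{\max}$ is returned
  conservatively to the cell above, so the invariant
  $0 \le \alpha \le \alpha_{\max}$ holds while total solids are conserved to
  round-off;
- zero-flux boundaries apply at the free surface and the tube bottom, and
  output samples take the last completed step before each requested time
  (no temporal interpolation).

```{r march}
f <- solve_sedimentation(alpha0 = 0.45, volume = 9e-6,
                         protocol = centrifuge_protocol(500, 600),
                         grid = solver_grid(n_cells = 100))
f
```

## Interfaces and recoveries

`locate_interfaces()` reads three heights off the solved field with
thresholds and sub-cell linear interpolation: the supernatant interface
$I_{ns}$ (topmost crossing of $\alpha = 10^{-3}$ scanning down), the
sediment interface $I_{sd}$ (crossing of $\alpha_{\max} - 10^{-3}$ scanning
up), and, from a second march for the white cells, the WBC front $I_{pW}$.

- **Plasma recovery** is the supernatant volume over the plasma content:
  $E_{plas} = V_{UL} / \bigl(V_{WB}(1 - H_e)\bigr)$ with $V_{UL}$ the tube
  volume above $I_{ns}$, clipped to $[0, 1]$.
- **Platelet recovery** uses a dimensional-analysis correlation. Buckingham
  reduction of the operating parameters leaves
  $\Pi_2 = V_t/(A L)$ (dead-volume ratio), $\Pi_3 = t_c/(L/u_\infty)$
  (spin time over the red-cell clearing time) and $\Pi_4 = a_c/g$;
  the platelet-to-plasma recovery ratio follows the power law
  $E_{PLT}/E_{plas} = \exp(c_2 + c_1 \Pi_2 \Pi_3 \Pi_4)$ with default
  coefficients $c_1 = -0.0122$, $c_2 = 0.5128$ (so the zero-argument limit
  is $e^{0.5128} \approx 1.67$: a short, gentle spin concentrates platelets
  in the supernatant relative to plasma). `fit_correlation()` refits
  $c_1, c_2$ (and optionally the exponents) to user records by least
  squares.
- **WBC recovery.** White cells settle in the same crowded suspension, so
  their hindrance is controlled by the total cell fraction: the WBC march
  uses the WBC Stokes velocity ($10\,\mu$m, $1065\,\mathrm{kg/m^3}$ —
  roughly half the red-cell velocity) but the hematocrit as the initial
  volume fraction of the field that sets the hindrance. The buffy-coat
  layer between the slower WBC front and the red-cell front has height
  $h = \max(I_{pW} - I_{ns}, 0)$, and
  $E_{WBC} = c_w\, V_{layer} / (\beta_o V_{WB})$ for a WBC volume fraction
  $\beta_o$ and capture efficiency $c_w$.

```{r recovery}
prp_recovery(0.45, 9e-6, centrifuge_protocol(500, 600))
```

## Protocol sweeps

Because the equation is dimensionless, one march per (geometry, hematocrit)
serves an entire acceleration sweep: acceleration only rescales $t^*$.
`recovery_curve()`, `critical_acceleration()`, `polar_curve()`,
`sensitivity_budget()`, `geometry_crossing()` and `optimization_map()`
build on this.

```{r sweep}
cv <- recovery_curve(sweep_spec(hematocrit_set = 0.37), t_c_min = 10,
                     include_wbc = FALSE)
critical_acceleration(cv)
```

The platelet curve rises steeply while plasma is still being cleared, peaks
at the critical acceleration, and decays as the correlation's loss term
(platelet sedimentation) takes over.

# Numerical accuracy

The scheme is deliberately first order and monotone: robust, positivity-
and bound-preserving, but diffusive. Practical consequences, quantified by
the test-suite oracles:

- **Front positions** (measured at mid-front) match the exact
  Rankine–Hugoniot/characteristics ODE to better than one cell.
- **Threshold interfaces** read the *edge* of a smeared front, not its
  middle, so $I_{ns}$ sits systematically a few cells above the exact
  discontinuity. Each cell of offset shifts $E_{plas}$ by
  $1/\bigl(n_{cells}(1-H_e)\bigr)$ — about 0.8 recovery points at the
  default 200 cells.
- **Derived optima inherit this bias.** Quantities like the critical
  acceleration depend on the curvature of $E_{PLT}(a_c)$ near a flat
  optimum and can shift by 10–30 % between the default grid and the
  converged limit; refining `solver_grid(n_cells = ...)` (400–1600) shows
  roughly first-order convergence. The sub-cell interpolation also leaves a
  small ($\sim \pm 0.005$) staircase ripple on sweep curves as interfaces
  cross cell boundaries.

For protocol *comparison* the default grid is fine (biases largely cancel
between nearby protocols); for absolute recovery figures or fitted optima,
use more cells and check convergence.

# Assumptions and limitations

- One-dimensional, axially aligned tube; no Coriolis or secondary flows,
  no wall effects, no tube inclination.
- Rigid, monodisperse red cells with a single Richardson–Zaki exponent;
  no aggregation (rouleaux), deformation or compressible-sediment
  rheology, so the packed bed is a hard cutoff at $\alpha_{\max}$.
- Platelet behaviour enters only through the fitted power-law correlation,
  not through an explicit platelet transport equation; the correlation is
  calibrated for single-spin protocols and should be refitted (see
  `fit_correlation()`) before extrapolating to very different tubes or
  spin programmes.
- The WBC treatment is a front-tracking approximation with a user-set
  capture efficiency $c_w$, intended for ordering protocols by leukocyte
  content rather than predicting absolute counts.
- Braking/acceleration ramps of the centrifuge are ignored: `spin_time` is
  time at the plateau acceleration.
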