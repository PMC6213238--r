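---
title: "Biodegradation kinetics of organic soil conditioners: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biodegradation kinetics of organic soil conditioners: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soildeg)
```

Organic soil conditioners — peat, composts, and strongly swelling polymer
hydrogels (SSPH) used in constructed soils and urban greening — are
themselves substrates for soil microorganisms. Their agronomic benefit
(water retention above all) decays as they are mineralized. This vignette
documents the models the package implements, the units and defaults it
assumes, and the numerical and design decisions behind the code. It is a
methods reference, not a tutorial; the README holds the quick-start worked
example.

## 1. The core kinetic model

The content $C$ of a conditioner in soil is modeled as first-order decay
with an optional replenishment input $L$:

$$\frac{dC}{dt} = L - kC,$$

with $k$ in yr⁻¹. Two characteristic times summarize any $k$:
the half-life $T_{0.5} = \ln 2 / k$ and the 95 %-decomposition time
$T_{0.95} = 3/k$ (since $\ln 20 \approx 3$). Their ratio is the universal
constant $3/\ln 2 \approx 4.33$, which the tests exploit as an identity
check. `characteristic_times()`, `decay_curve()` and
`steady_state_input()` implement this layer.

### From respiration to a decay constant

The decay constant is estimated from basal respiration measured in closed
vials. The chain is:

1. `respiration_rate()` converts a headspace CO₂ increment to a specific
   rate $U_m$ (mg CO₂ kg⁻¹ h⁻¹) by the ideal gas law:
   $U_m = 1000\,P M V \Delta X\% / (100\,R\,T\,m_s\,\Delta t)$ with the
   gas volume in m³ internally (inputs are mL).
2. The carbon-based flux $u$ (mg C kg⁻¹ h⁻¹) relates to the CO₂ flux by
   the mass ratio 12/44 (`carbon_flux_from_co2()`).
3. `k_from_respiration()` converts $u$ to a daily carbon loss percentage
   $p = 0.24\,u/c$ (where $c$ is the substrate carbon content in percent,
   and 0.24 collects 24 h/day and the unit conversions) and then to
   $k = t_{bio}(\ln 100 - \ln(100 - p))$.

$t_{bio}$ is the number of biologically active days per year. The package
default is 365 (continuous activity, the laboratory-equivalent convention);
for field regimes with a cold season a value near 200 is more realistic and
can be supplied explicitly. This is a deliberate exposed knob, not a
constant.

We allow $k = 0$ (no measurable respiration) rather than requiring
$k > 0$: a zero flux is a legitimate measurement, and the characteristic
times are then reported as `Inf`.

## 2. Hydrothermal response surface

Respiration responds multiplicatively to temperature and moisture:
$U = U_{max} \cdot m(T) \cdot f(W)$.

* **Temperature.** $m(T) = Q_{10}^{(T - T_m)/10}$ with defaults
  $Q_{10} = 2$ and $T_m = 30$ °C. The factor is defined on
  $[0, T_m]$; above $T_m$ extrapolation must be requested explicitly
  (`extrapolate = TRUE`), because the empirical law was calibrated below
  the optimum and real soils pass a thermal optimum.
* **Moisture.** The extremum law
  $f(W) = (W/W_m)^a \left((1-W)/(1-W_m)\right)^b$ on relative moisture
  $W \in (0,1)$, with the optimum fixed by the shape parameters:
  $W_m = a/(a+b)$. $f$ is 0 at both endpoints and 1 at $W_m$.
* An alternative single-exponential law $k(T) = k_0 e^{sT}$
  (`exp_rate_law()`) covers hot-climate data where no optimum is reached;
  its implied $Q_{10}$ is $e^{10s}$.

`fit_moisture_response()` fits $(a, b)$ (and optionally the scale
$U_{max}$) by Levenberg–Marquardt least squares. Two design points matter:

* **Log-parameterization.** $a, b, U_{max}$ are fitted as
  $e^{\lambda}$ to keep them positive without active box constraints; a
  one-step refit on the natural scale then provides standard errors and
  p-values at the solution.
* **Normalization.** With `normalize = TRUE` (default) the data are
  pre-scaled by their maximum, but the scale is *not* pinned to that
  maximum — a free scale factor is co-fitted. Pinning would bias
  $(a, b)$ whenever the measurement grid misses the true optimum, which is
  essentially always.

## 3. Forced decay under a variable climate

When temperature (and optionally moisture) varies in time, the decay
constant becomes a composition $k(t) = k(T(t))$ or
$k(t) = k_{max} m(T(t)) f(W(t))$, and the retained fraction follows
$dC/dt = -k(t) C / 8760$ with $t$ in hours (one year = 8760 h; diurnal and
seasonal forcings share a single time axis).

* Forcings are sinusoids (`sinusoid_forcing()`, including the arid diurnal
  regime `arid_forcing()` with mean 38.14 °C, amplitude 4.45 °C, period
  23.85 h) or tabulated series interpolated with a monotone
  (shape-preserving) spline, range-checked so the simulation never
  extrapolates temperature silently.
* `simulate_decay()` integrates with `deSolve::ode` (lsoda,
  `rtol = 1e-8`, `atol = 1e-12`). The state is the retained *fraction*,
  scaled by the dose afterwards, so loss percentages are exactly
  independent of the initial content.
* Two independent cross-checks guard the integrator:
  `simulate_decay_stepwise()` is a piecewise-exact midpoint-frozen-rate
  oracle with no ODE machinery, and for a sinusoidal forcing under the
  exponential rate law the cycle-mean rate has the closed form
  $\bar k = k_0 e^{sT_0} I_0(s A)$ (modified Bessel function,
  `mean_rate_sinusoid()`).

## 4. Depth attenuation and burial-depth nomographs

Biological activity declines with depth as
$U_m(h) = U_\infty + a e^{-bh}$. By analogy with the characteristic
times, $H_{0.5} = \ln 2 / b$ and $H_{0.95} = 3/b$ bound the biologically
active layer. The burial depth needed to slow conditioner decay $n$-fold is

$$H = \ln(n)/b,$$

which ignores the deep asymptote $U_\infty$; `burial_depth_floored()`
solves the exact equation $U_\infty + a e^{-bH} = (U_\infty + a)/n$ and
errors when the target is unattainable (below the asymptote). The simple
form is the headline design rule; the floored form quantifies its error.
`nomograph_table()` tabulates $H(n)$ either against the attenuation
coefficient $b$ (default 0.1–1 cm⁻¹) or against the active-layer depth
$H_{0.95}$ (default 6–30 cm, with $b = 3/H_{0.95}$). Note that reading a
published nomograph graphically can differ from the analytic value by a
centimeter or more; the package always reports the analytic solution.

## 5. Water retention

Conditioner performance is tracked with the van Genuchten retention curve
under the Mualem constraint $m = 1 - 1/n$:
$\theta(\psi) = \theta_r + (\theta_s - \theta_r)(1 + (\alpha\psi)^n)^{-m}$.
`fit_wrc()` requires at least five pressure levels including one at or
below 10 kPa (otherwise $\theta_s$ is unidentified) and rejects flat
curves as fit errors. `capacity_metrics()` reports total capacity
($\theta_s$) and field capacity at a configurable matric potential; the
package default of 33 kPa is a convention, not physics — pass 10 kPa for
sandy substrates if your laboratory uses that convention.

## 6. Synthetic data generators

Every input class has a seeded generator (`gen_response_grid()`,
`gen_decay_series()`, `gen_depth_profile()`, `gen_wrc_dataset()`, plus the
`moscow_like_forcing()` annual temperature cycle, which is a synthetic
stand-in for a humid-temperate monitoring series, not observational data).
Design rules:

* The generating parameters are embedded in a `truth` attribute so
  recovery tests never re-derive them.
* Identical seed and configuration give identical output, byte-for-byte
  after writing; the session RNG stream is saved and restored, so
  generators never perturb user code.
* Mass-loss series start at exactly 100 % by definition; noise applies
  from the second point on. The seasonal mode modulates $k$ by a
  normalized Q10 temperature factor integrated piecewise-exactly, so the
  long-run mean constant still equals the nominal $k$.
* Generators are for validation and teaching. They encode the package's
  own models, so recovering parameters from them demonstrates correctness
  of the estimation machinery, not truth of the models.

## 7. Numerical choices

* All nonlinear fits use `minpack.lm::nlsLM` with a tolerance ladder
  (`ftol = ptol` from 1e-15 down to the square root of machine epsilon,
  `maxiter = 1000`): the tight end recovers noise-free parameters to
  ~1e-6 relative, and the ladder retries when the tight setting drives
  the iterates into a numerically singular corner. Depth-profile fits
  additionally fall back to the two-parameter pure-exponential model when
  the fitted asymptote is indistinguishable from zero.
* Starting values are derived from the data (log-linear slopes for
  exponentials, the curve midpoint for $\alpha$ in the retention fit),
  never hard-coded magic numbers.
* The ODE horizon is partitioned into at least 3 and by default 400
  output points; reported losses at interior times use log-linear
  interpolation of the trajectory, which is exact for piecewise-constant
  rates.

Typical problem sizes are tiny: tens of observations per fit, a few
hundred ODE output points, simulation horizons up to a few years of hours.
Everything in the test suite runs in seconds on one CPU.

## 8. Limitations

* First-order kinetics with a single pool; no multi-pool or Michaelis–
  Menten behavior.
* The temperature and moisture factors are empirical; the package does not
  attempt mechanistic microbial models.
* Moisture forcing is accepted but no water-balance model is provided —
  couple an external soil-water simulation if needed.
* Field variability (spatial heterogeneity, substrate aging, microbial
  succession) is outside scope; the generators model measurement noise
  only.
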