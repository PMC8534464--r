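---
title: "Modelling osmotic-dehydration mass transfer with osmokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling osmotic-dehydration mass transfer with osmokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osmokin)
```

## The measurement model

Osmotic dehydration immerses fruit in a hypertonic solution (typically
60–70% w/w sucrose); water flows out of the tissue while solute flows in.
An experiment observes, per treatment and sampling time, the batch mass
`Wf` (g) and its moisture fraction `Xf`, plus one time-0 record giving the
initial `Wi` and `Xi`. `build_kinetics()` converts these into water loss
(WL), solid gain (SG) and weight reduction (WR), all as percent of `Wi`:

$$WL = 100\,\frac{W_i X_i - W_f X_f}{W_i},\qquad
  SG = 100\,\frac{W_f(1-X_f) - W_i(1-X_i)}{W_i},\qquad
  WR = 100\,\frac{W_i - W_f}{W_i}.$$

`WR = WL − SG` is an algebraic identity, not an empirical fact; the
package asserts it on every series it builds or generates, which makes it
a cheap integrity check on parsed data. Negative WL or SG values are kept:
a fruit can transiently take up water or leach solids early in the
process, and clamping would bias fits. Moisture columns whose values
exceed 1.5 are interpreted as percentages and divided by 100 (a fraction
cannot exceed 1; real datasets mix both conventions), with a warning.
Internally all times are seconds — the published rate constants (`S` in
s⁻¹, Peleg `k₁` in s·%⁻¹) force that convention — while the raw CSV schema
uses hours, matching how such experiments are logged.

## The four kinetic models

Write `Y(t)` for WL or SG. Two models act directly on the percent scale:

* **Peleg**: $Y(t) = t/(k_1 + k_2 t)$. $1/k_1$ is the initial rate and
  $1/k_2$ the equilibrium value $Y_\infty$; both constants must be
  positive, which the fit enforces with box constraints rather than by
  silently reflecting signs.
* **Azuara**: $Y(t) = S\,t\,Y_\infty/(1 + S\,t)$, derived from a mass
  balance. It is the same hyperbola as Peleg under
  $k_1 = 1/(S Y_\infty)$, $k_2 = 1/Y_\infty$ — a fact the test suite uses
  as an exact cross-check — but it is traditionally *estimated*
  differently: for $t>0$, $t/Y = 1/(S Y_\infty) + t/Y_\infty$ is a
  straight line, so an OLS fit of $t/Y$ on $t$ gives
  $Y_\infty = 1/\text{slope}$ and $S = \text{slope}/\text{intercept}$.
  The linearization is exact on model-true data; on noisy data it weights
  points differently from direct NLS, so `fit_azuara()` also offers
  `method = "nls"` as a cross-check.

Two models act on the *unaccomplished* dimensionless ratio
$y(t) = 1 - Y(t)/Y_\infty$, produced by `to_dimensionless()`:

* **Crank (sphere)**: the series solution of Fick's second law for a
  sphere with constant surface condition,
  $y(t) = (6/\pi^2)\sum_{n\ge1} n^{-2}\exp(-n^2\pi^2 D_e t/r^2)$,
  truncated at 30 terms. The sphere radius comes from caliper geometry,
  $r = (\text{length}+\text{width})/4$; for the berries used as the
  reference case this is 3.29 mm. The only free parameter is the
  effective diffusivity $D_e$ (m²·s⁻¹).
* **Page**: the empirical stretched exponential $y(t) = \exp(-A t^B)$.

Because the ratio transform is affine in $Y$, the $R^2$ of a ratio-space
fit equals the $R^2$ of the same predictions re-expressed in percent, so
ranking models by $R^2$ across the two spaces is well defined; RMSE is
reported in each fit's native units (percent vs dimensionless) plus a
percent-scale RMSE for cross-model comparison and tie-breaking.

### Numerical choices

* **Truncation.** At 30 terms the series is converged far beyond
  measurement precision for Fourier numbers $F_o = D_e t/r^2 \ge 0.02$
  (the suite checks agreement with a 10,000-term sum to 1e−10). At
  $t = 0$, however, the truncated sum is
  $(6/\pi^2)\sum_1^{30} n^{-2} = 0.98007$, not 1. `crank_ratio()` returns
  the analytic value 1 at $t=0$ by default and exposes the truncated
  behaviour via `exact_t0 = FALSE` for fidelity checks.
* **Starting values** are deterministic closed forms, so fits are exactly
  reproducible: Peleg starts at $k_2 = 1/(1.05\,\max Y)$ and
  $k_1 = t_1/Y_1$; Azuara starts (and by default ends) at its own
  linearization; Page starts at the log-log regression
  $\ln(-\ln y) = \ln A + B\ln t$; Crank starts at the first-mode
  log-linear slope, $\ln y \approx \ln(6/\pi^2) - \pi^2 D_e t/r^2$ (the
  first mode dominates to within 1e−3 for $F_o \ge 0.2$).
* **Optimisers.** Peleg, Azuara-NLS and Page use bounded
  Levenberg–Marquardt (`minpack.lm::nlsLM`, lower bounds 1e−12, ftol =
  ptol = 1e−15, up to 10,000 function evaluations). The Crank fit is a
  one-dimensional minimisation, done on $\log_{10} D_e$ with
  `stats::optimize()` bracketed three decades either side of the
  first-mode start — scale-free, derivative-free and deterministic; a
  solution at the bracket edge is flagged (`De_at_search_bound`) rather
  than silently returned.
* **$t = 0$ rows** are included in NLS fits (every model is defined
  there) but necessarily excluded from the Azuara linearization, where
  $t/Y$ is 0/0.
* **Degenerate inputs** (constant series, a ratio identically 1, fewer
  than three informative points, a non-decaying ratio) raise classed
  errors (`osmokin_fit_failure`, `osmokin_linearization_invalid`) instead
  of returning garbage parameters; `compare_models()` catches them per
  model and ranks the model out with its message so one pathological
  series does not abort a batch analysis.

### Equilibrium convention for the ratio models

The dimensionless transform needs a $Y_\infty$ that the data never
reaches. Following the usual practice for this model set, the Crank and
Page fits take $Y_\infty$ from the Peleg fit's $1/k_2$; whether Page
should instead use Azuara's equilibrium is genuinely open, so
`compare_models(y_inf_source = "azuara")` switches the convention — one
consistent choice for both ratio models either way. Equilibria are always
reported from the *unrounded* fitted $k_2$: published tables that round
$k_2$ to three decimals imply equilibria that differ by ~1–2% from
$1/k_2$ of the printed value, and reporting from the unrounded estimate
avoids baking that rounding into downstream diffusivities.

## What the synthetic generator emulates — and what it does not

`simulate_kinetics()` reproduces the *structure* of a replicated
dehydration experiment: sampling at 0, 0.5, 1, 1.5, 2, 3, 4, 5 and 10 h;
WL and SG trajectories following any of the four models with parameters
of the published magnitude (`reference_kinetic_params()` carries the
reference set); independent additive Gaussian noise on WL and SG at each
$t > 0$, default σ = 1 percentage point (the magnitude of reported
error bars at these conditions); and `WR = WL − SG` by construction.
At $t = 0$ the series is exactly 0 — WL and SG are defined relative to
the initial state, so the time-0 observation carries no error.
`inverse_mass_balance()` then maps trajectories back to raw
mass/moisture pairs ($W_f = W_i(1 - WR/100)$,
$X_f = (W_i X_i - W_i\,WL/100)/W_f$), refusing trajectories whose implied
moisture leaves $[0,1]$; feeding the result through `build_kinetics()`
reproduces the generating WL/SG to round-off, which is the package's
end-to-end closure test.

The generator deliberately does **not** model: correlated errors between
WL and SG (the same weighing enters both, so real errors are coupled);
heteroscedastic noise growing with the measured quantity; fruit-to-fruit
variability in geometry or initial moisture; or any mechanistic vacuum
physics (hydrodynamic impregnation, gas expansion) — vacuum vs
atmospheric treatments differ only through their kinetic parameters.
Passing recovery tests on these data therefore demonstrates estimator
correctness and numerical stability, not robustness to every failure mode
of real colorimeter and oven-moisture data.

Seeds are mandatory (both in R and in the CLI) and the generator runs
inside `withr::with_seed()`, so identical configurations are bit-identical
and the caller's RNG stream is untouched.

## Quality metrics

Colour change is the Euclidean CIELAB distance
$\Delta E = \sqrt{\Delta L^2 + \Delta a^2 + \Delta b^2}$ against a fresh
(time-0) reference; more elaborate formulas (ΔE94, ΔE2000) are out of
scope. Because $\Delta E$ is convex in the readings, the mean of
per-reading $\Delta E$ values exceeds the $\Delta E$ of mean readings
(Jensen); published tables rarely state which was used, so
`summarize_color_change()` reports both (`dE_mean`, the reported
statistic, and `dE_of_means`), and both a per-treatment grand-mean
reference and a per-repetition reference are supported.

Concentrations measured per 100 g of *dehydrated* fruit overstate
retention, since dehydration concentrates what remains.
`to_initial_mass_basis()` multiplies by $(1 - WR/100)$ — equivalently
$c\,W_f/W_i$ — to express them per 100 g of initial fresh weight;
`percent_loss()` handles constituents such as titratable acidity
(e.g. 1.14% → 0.51% malic acid is a 55.3% loss). Water activity, density,
pH and soluble solids are carried as data columns only: no kinetic model
is defined for them here.

## Problem sizes and reproducibility

All simulation-based checks run at the experiment's own scale — nine
sampling times, up to three replicates — which keeps a full test run
under half a minute: 200 simulated experiments for the noisy Peleg
recovery (median relative error of $k_2$ ≈ 0.5% at σ = 1) and 100 for
the model-ranking study (the generating Peleg model ranks first for
water loss in ≥ 90% of replicated experiments when fitting
replicate-mean series; on a single noisy replicate an empirical
two-parameter model occasionally wins, as the README example shows).
`run_full_analysis()` writes a manifest with hashes of its inputs and
ranked summary so a rerun can be verified byte-for-byte.

## Known limitations

* The Azuara linearization inherits the classical estimator's implicit
  weighting; with strongly heteroscedastic data direct NLS on the
  hyperbola is preferable (`method = "nls"`).
* The Crank fit assumes constant diffusivity, uniform initial
  concentration, negligible shrinkage and a perfectly spherical fruit;
  $D_e$ is an *effective* lumped coefficient, not a physical diffusion
  constant.
* Model ranking by $R^2$/RMSE is descriptive; the package deliberately
  omits information criteria and bootstrap intervals rather than imply a
  formal model-selection procedure the underlying data cannot support.
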