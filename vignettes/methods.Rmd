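---
title: "Model description and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model description and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catchrt)
```

## The model

`catchrt` simulates watershed-scale solute dynamics with a deliberately
parsimonious structure: a bucket hydrology drives advective transport and
biogeochemical reactions in three well-mixed "effective" zones —

* **SF**, a transient surface zone carrying quick flow `q_sf`;
* **SZ**, the shallow soil zone (upper dynamic store + soil moisture +
  passive storage), carrying lateral flow `q_sz` and recharging the deep
  zone via percolation `q_perc`;
* **DZ**, the deep groundwater zone (lower dynamic store + passive
  storage), supplying baseflow `q_dz`;

plus a snowpack that accumulates precipitation chemistry and releases it
with melt (no reactions occur in snow; melt has the chemistry of the pack).
Stream concentration is the instantaneous flux-weighted mixture of the three
pathways. For every primary species *i* and zone, the model solves a mass
balance of the form

$$\frac{d(C_i V_w)}{dt} = \sum_{\text{in}} Q\,C_{\text{in},i}
  - \sum_{\text{out}} Q\,C_i + R_i,$$

with water volumes (mm, i.e. L/m²) and fluxes (mm/day) supplied by the
hydrology, and `R_i` (mol/m²/day) the summed kinetic reaction rates scaled
by stoichiometry. Infiltrating water has the flux-weighted chemistry of rain
and snowmelt; water entering SF and water infiltrating SZ share that
chemistry (quick flow has little contact time, so surface-zone reactions are
off by default and can be enabled per configuration).

**Primary vs secondary species.** Only primary-component totals are
time-stepped. Secondary species (e.g. CO₂(aq), CO₃²⁻, OH⁻, sorbed DOC)
follow from the primaries through mass-action laws; activities equal
concentrations (dilute-solution convention), solids have activity 1, and
pseudo-gases (soil CO₂) a prescribed activity. Dissolved inorganic carbon is
*not* a species but a reporting aggregate CO₂(aq)+HCO₃⁻+CO₃²⁻; reactions
written against DIC carry their carbon on the bicarbonate component and
speciation redistributes it.

## Rate laws

Kinetic rates follow `r = k · A · f(T) · f(Sw) · f(Zw) · <law>` with
`k` (mol/m²/s, converted to per-day) and `A` the constant reactive surface
area per m² of catchment, computed once as SSA (m²/g) × reactive substrate
mass (g/m²). `<law>` is either the transition-state-theory departure term
`(1 − IAP/Keq)` (signed: negative means precipitation) with optional
catalyst activities, or a product of Monod `C/(C+K_M)` and inhibition
`K_I/(C+K_I)` terms. Monod terms on solid or gas substrates act on a
prescribed constant availability (mol/L equivalent), reflecting substrates
abundant enough not to be tracked.

Environmental factors:

* `f(T) = Q10^(|T−20|/10)` as printed in the source family of models. The
  absolute-value exponent makes rates *rise* below 20 °C, which contradicts
  the usual reading of Q10 (and the seasonality such models report), so a
  `signed_q10` switch selects `Q10^((T−20)/10)`. The function default is the
  printed form; **both shipped example configurations set
  `signed_q10: true`**, because respiration and leaching peaking in summer
  is the behaviour the examples are meant to illustrate.
* `f(Sw)` is a piecewise power law peaking at the critical saturation
  `Sw_c`: `(Sw/Sw_c)^n` below, `((1−Sw)/(1−Sw_c))^n` above; `n = 0` disables
  it. `Sw_c` values outside (0,1] are accepted deliberately — published
  parameter tables use 1.25, 1.7 (always on the rising branch) and 0 (always
  on the falling branch), and the formula is well defined there.
* `f(Zw) = exp(−(αβ)·Zw)`: only the product αβ is prescribed, so the
  exponential-in-depth reading is the only one parameterizable by it; a
  positive product makes rates increase as the water table rises.

## Speciation

Unknowns are log₁₀ concentrations of the primaries. Each secondary is
resolved against the primaries through its defining equilibrium reaction
(substituting through intermediate secondaries; a configuration whose
secondaries cannot be expressed in primaries is rejected at build time), and
a damped Newton–Raphson iteration (step cap 1 log₁₀ unit per component,
≤100 iterations, relative mole-balance tolerance 1e-10, several fallback
starts) solves the component balances. Components with exactly zero totals
(e.g. no sorption sites) drop out of the solve; proton balances may be
negative (hydroxide carries −1). Tests pin the solver against a brute-force
2-D grid refinement and the closed-form carbonate (Bjerrum) split at fixed
pH.

## Numerical scheme

Operator splitting (sequential non-iterative approach): within each step,
transport first, then reactions per zone, then re-speciation.

* **Transport** is fully implicit (backward Euler) in both concentration and
  end-of-step storage: unconditionally stable, exactly mass-conserving by
  construction. Percolation carries the shallow zone's end-of-step
  concentration into the deep zone within the same step. Immobile species
  (sorption sites, sorbed mass) are retained in place as constant mass.
  Evapotranspiration removes water only, concentrating solutes — the model
  never fractionates solutes into vapour.
* **Reactions** use a Crank–Nicolson (trapezoidal) step solved by a chord
  Newton iteration on the end-of-step totals (finite-difference Jacobian,
  relative tolerance 1e-11); on failure the step is halved, up to 12 times,
  before erroring with diagnostics. Reported rates are time-averaged so that
  Δtotal = Σ stoich × mean rate × Δt/V holds to machine precision. An order
  test confirms the expected O(Δt²) convergence on a smooth Monod decay.
* **Time step**: 1 day by default; integer fractions of a day subdivide each
  day with fluxes held constant and storages interpolated linearly. Halving
  the step moves annual mean stream concentrations of the carbon example by
  less than 1%.

The hydrology itself is the standard single-column bucket structure:
degree-day snow, `(SM/FC)^β` recharge partitioning,
soil-moisture-limited ET, an upper store with capped percolation and
two linear outlets, and a linear lower store. One deliberate deviation:
quick flow is capped at same-day rain+melt, because the surface zone that
routes it to the stream is fed only by rain and melt; the upper store
retains the remainder. This keeps every zone's water balance closed to
machine precision (the capped days are rare no-inflow recession days).

Shallow-zone saturation is `min(1, SM/FC)`; deep-zone saturation uses the
stored volume over pore volume; water-table depth is
`max(0, depth − (V_w/1000)/porosity)` — the source models use these
quantities without defining their bucket-level computation, so the simplest
defensible mappings are used and are configuration-visible.

**Spin-up.** Runs damp initial-condition transients by simulating the first
`spinup_days` of forcing once before the recorded pass. Spin-up carries
*concentrations* only: storages restart on day-1 hydrology and the snowpack
restarts empty, so the recorded pass sees no storage discontinuity. The
carbon example spins up one year; the nitrogen example spins up two, because
the deep zone's turnover (~0.9 yr at the example's geometry) leaves a
visible trend after a single year.

## The synthetic climate

The weather generator emulates a humid continental, seasonally
snow-influenced headwater climate: ~1,320 mm/yr precipitation with 20–30%
falling as snow, mean annual temperature ~5 °C, and a spring snowmelt
discharge peak. Temperature is a sinusoid (minimum late January, amplitude
11 °C) plus Gaussian noise (sd 3.5 °C); wet days are Bernoulli (p = 0.45,
mildly summer-weighted) with gamma intensities (shape 0.7) scaled to the
annual normal; PET is temperature-indexed (0.25 mm/day/°C above freezing,
≈45% of precipitation as ET). Identical spec and seed reproduce the series
bit-for-bit.

What it does **not** emulate: multi-day storm persistence, rain-on-snow
event structure, inter-annual climate variability beyond sampling noise,
and seasonally varying precipitation chemistry (constant by default). Tests
passing on this forcing therefore demonstrate internal consistency and the
qualitative flow-path mechanisms, not predictive skill for any real
catchment.

## The shipped examples and their free parameters

The two example networks carry their published rate parameters (log₁₀ k,
SSA, Keq, K_M, Q10, n, Sw_c, αβ) verbatim — a literal assertion table in the
test suite checks every value. What such tables do not print are the
reactive substrate *abundances* behind each `A` term, initial and
precipitation chemistry, passive storage, and zone geometry; these were
chosen once, at field-plausible magnitudes, so that the printed networks
exhibit the behaviours the examples exist to demonstrate:

* **Carbon.** Respiration masses (150 g/m² effective reactive organic
  carbon in SZ, 35 kg/m² in DZ) give stream DOC at the mg C/L scale with
  deep respiration consuming percolated DOC. The shallow (pedogenic)
  carbonate is scarce (0.05 g/m²) and therefore kinetically limiting, while
  the deep carbonate is abundant and equilibrium-pinned. This asymmetry is
  forced by the printed stoichiometries: with 1.1 Ca : 0.5 C (shallow) and
  0.9 Ca : 0.7 C (deep) sharing one Keq, *equilibrium in both zones* would
  make Ca highest where DIC is lowest — i.e. the shallow zone — and
  calcium dilution would be impossible. With scarce shallow carbonate the
  example reproduces the expected pattern set: DOC flushing (positive C-Q
  rank correlation), DIC and Ca dilution (negative).
* **Nitrogen.** Deep leaching and uptake substrates are set tiny (their
  rates are effectively zero), deep denitrification is abundant enough to
  deplete deep nitrate, and passive storages are smaller than in the carbon
  example (the nitrogen network is an uncalibrated numerical experiment;
  passive storage damps concentration dynamics and is a per-study
  calibration quantity). Toggling `Denitrification_DZ` off flips the stream
  nitrate C-Q pattern from flushing to dilution — the reaction's diagnostic
  signature.

## Problem sizes in the test-suite

The suite runs entirely on synthetic data: 2-year daily simulations for the
example networks and the conservative-tracer oracle comparison (an
independently coded explicit mixing-cell integration at 100 substeps/day),
a 2,500-day constant-forcing run for the steady-state identity, 10 years of
generated weather for the climate normals, and small closed-form or
brute-force oracles everywhere else. The full suite completes in about two
minutes on one core.

## Known limitations

* One column; no lateral heterogeneity, hot spots, or in-stream processing.
* No activity-coefficient model, no temperature dependence of Keq, no
  isotopes; mineral surface areas constant in time.
* The daily implicit transport step does not resolve sub-daily transients of
  the fast surface store (its residence time can drop below a day during
  melt events); zone and stream chemistry at the daily reporting scale are
  unaffected.
* The printed carbonate stoichiometries are not charge- or mass-balanced;
  they are applied literally (fidelity over thermodynamic orthodoxy), so pH
  evolves only through transport and the carbonate speciation reactions.
* Zeroth-order rate laws (plant uptake) can in principle exhaust a pool;
  the integrator halves its step and ultimately errors rather than silently
  flooring, so pathological parameterizations fail loudly.
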