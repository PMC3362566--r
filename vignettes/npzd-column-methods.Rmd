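---
title: "Methods: the NPZD column model and its skill statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the NPZD column model and its skill statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npzdcolumn)
```

## Scope and model structure

`npzdcolumn` implements the biogeochemical half of a coupled shelf
modelling system at desk scale: the four-compartment nitrogen-based NPZD
kinetics with a dynamic chlorophyll:C ratio, a 1-D vertical column with
light attenuation, diffusion, sinking and prescribed upwelling, and the
statistics used to judge such models against satellite fields. The 3-D
hydrodynamics that normally surrounds this module (resolved advection,
KPP mixing, atmospheric forcing, data assimilation cycling) is
deliberately absent; vertical diffusivity, temperature, irradiance and
upwelling velocity are prescribed forcings.

The four compartments N, P, Z, D (mmol N m⁻³) exchange through six
fluxes: nitrate uptake `U = mu * P`, grazing `G = g(P) * Z` partitioned by
the assimilation coefficient `beta` (assimilated fraction to Z, the rest
to D), linear phytoplankton and zooplankton mortality to detritus,
zooplankton excretion to nitrate, and detritus mineralisation to nitrate.
Because every term is a transfer between compartments, the nitrogen
tendencies sum to zero identically; this is asserted as a property test
over random states.

### Growth and photoacclimation

Realised growth follows a Geider-type formulation:

$$\mu = \mu_{NT}\left(1 - e^{-\alpha\,\mathrm{PAR}\,\theta/\mu_{NT}}\right),
\qquad \mu_{NT} = \mu_0\,a_T^{\,T}\,\frac{N}{K_N+N}.$$

The exact equation set behind the operational code is not published with
it, so two choices here are this package's own, exposed as parameters
rather than hard-wired:

* **Temperature dependence.** An Eppley curve `mu0 * a_T^T` with
  `mu0 = 0.59` d⁻¹ and `a_T = 1.066`, the standard choice in this model
  family. Setting `a_T = 1` removes the dependence.
* **Light and nutrient interaction.** Multiplicative nutrient × light
  limitation with the exponential light term, which reduces to
  `alpha * PAR * theta` under light limitation and saturates at `mu_NT`.
  The forms are documented, not claimed to be bit-identical to any
  operational implementation.

Chlorophyll a is a fifth tracer. Carbon fixed is converted at the
Redfield ratio (6.625 mol C mol N⁻¹, 12.011 g C mol⁻¹) and a fraction

$$\rho_{chl} = \theta_{max}\,\frac{\mu}{\alpha\,\mathrm{PAR}\,\theta}
\in [0, \theta_{max}]$$

is allocated to chlorophyll synthesis. As PAR → 0 the ratio tends to
`theta_max`; that limit is returned explicitly when the denominator
vanishes, avoiding 0/0. Chlorophyll losses (grazing, mortality) are taken
in proportion to the phytoplankton nitrogen lost at the *current* θ, so
losses can never change θ; combined with ρ ≤ θ_max this makes
0 < θ ≤ θ_max provable along trajectories, and the bound is tested over a
light × nutrient sweep.

### Parameters

All rates are per day; the defaults (see `bio_params()` and the shipped
`params_default.conf`) are the operational western-Iberian values:
attenuation `k_w = 0.04` m⁻¹ and `k_chla = 0.024` m⁻¹ (mg Chla m⁻³)⁻¹,
P–I slope `alpha = 1`, `theta_max = 0.03` mg Chla (mg C)⁻¹, half
saturations `K_N = 1.5` and `K_P = 1.0` mmol N m⁻³, `g_max = 0.9` d⁻¹,
`beta = 0.75`, mortalities `m_P = 0.03` and `m_Z = 0.1` d⁻¹, excretion
`e_Z = 0.1` d⁻¹, mineralisation `r_D = 0.05` d⁻¹, sinking `w_P = 0.5` and
`w_D = 5` m d⁻¹, and a surface PAR fraction of 0.43. Zooplankton
excretion is applied to biomass (a constant specific rate), not to
ingestion. The river table ships with the package
(`river_table()`); its nitrate column's mass basis is ambiguous in the
source material, so `river_concentrations()` makes the interpretation an
explicit argument (`"nitrogen-mass"` by default, dividing by 14.007 g
mol⁻¹; `"nitrate-mass"` divides by 62.004).

## Numerics

**Biology (positivity + conservation).** A plain explicit Euler step can
drive a compartment negative; a plain Patankar step (implicit damping of
each compartment's sinks) is positive but breaks exact nitrogen
conservation, because recipients would receive the *undamped* flux. The
stepper therefore damps each donor's total outgoing flux by
`1/(1 + dt·out/X)` and transfers the **realised** flux to the recipients
— the one-sided modified-Patankar–Euler construction. It is first-order
consistent, unconditionally positive, and conserves N+P+Z+D to machine
precision; closed 100-day box and column runs hold total nitrogen to
better than 10⁻¹⁰ relative in the test suite. For the slow linear decays
this scheme integrates `X/(1+dt·m)` per step, so a 300-s step recovers a
0.03 d⁻¹ mortality with relative bias ~`dt·m/2 ≈ 5e-6`, far inside the
1 % acceptance band.

**Operator splitting.** Each `column_step()` applies, in fixed order:
optics → biology → sinking → upwelling → diffusion. Light must see the
current chlorophyll (self-shading uses the instantaneous field; the error
is O(dt)); mixing last smooths splitting artifacts. The splitting is
first order; halving dt changes the bloom-scenario answer by a shrinking
amount (Richardson test).

**Transport.** Diffusion is backward-Euler implicit with zero-flux
boundaries, solved by a Thomas tridiagonal solve (compiled, shared across
the five tracers); its flux form conserves inventory to round-off and the
Gaussian-pulse variance matches the heat kernel σ²(t) = σ₀² + 2·Kv·t to
1 % after a day at dz = 0.5 m. Sinking and upwelling are first-order
upwind with internal sub-stepping so `w·dt_sub ≤ min(dz)`; on a uniform
grid the centre of mass of a pulse descends exactly `w·t`, which is how
the sinking velocities are recovered in the acceptance run. The bottom
boundary defaults to `retain` (sinking matter accumulates in the bottom
cell) so conservation tests are exact; `export` is available for realism.
The upwelling deep boundary supplies a configurable deep nitrate
concentration (0 for the other tracers).

**Defaults.** Column 200 m deep, dz = 2 m, dt = 300 s, all configurable.
Depth is positive down with the surface at 0; PAR at a cell centre uses
half-cell attenuation, making the clear-water profile exact at cell
edges. Degenerate inputs are rejected loudly: negative concentrations,
PAR or irradiance are domain errors, a non-finite or negative field after
a step aborts with the offending cell named, and a scenario shorter than
the requested run is a configuration error.

## The synthetic forcing scenario

`upwelling_event_scenario()` is a first-class, tested generator, not a
fixture: it encodes the study conditions of a two-week summer
upwelling event on a mid-latitude shelf. Wind is not modelled (the column
has no momentum equation); the upwelling-favourable wind narrative is
mapped directly onto cosine-ramped schedules of upwelling velocity
(default peak 5 m d⁻¹ — a typical eastern-boundary event magnitude — over
days 10–24 of a 40-day scenario) and mixed-layer diffusivity (10⁻⁵ m² s⁻¹
background to 10⁻³ m² s⁻¹ in the upper 30 m during the event). Irradiance
is a clear-sky diurnal half-sine peaking at 800 W m⁻², temperature dips
from 16 °C to 13.5 °C while upwelled water is at the surface, and the
deep nitrate reservoir is 10 mmol N m⁻³ with an initial nutricline
between 20 and 60 m — all values a coastal biogeochemist would call an
ordinary summer event, chosen once and kept fixed. Under these defaults
the simulated surface chlorophyll rises more than fivefold over its
pre-event background and decays after relaxation, which the acceptance
suite checks as a qualitative property.

What the generator does **not** emulate: mesoscale variability,
horizontal advection of the bloom, realistic cloud statistics, the
wind-to-upwelling transfer function, or KPP-style interactive mixing.
Passing tests therefore demonstrate correct kinetics, transport and
bookkeeping under idealised forcing — not skill against real satellite
data. `synth_obs()` produces satellite-like series (truth + seeded
Gaussian noise + gaps) purely as a test double for the statistics.

## Skill statistics

`model_bias()` is the time-mean model-minus-observation difference with
pairwise deletion of missing data; `bias_map()` applies it per grid
point. The low-pass filter family and cutoff are not fixed by convention
anywhere authoritative, so `lowpass()` defaults to a 5th-order
Butterworth at a 40-h cutoff applied forward–backward (zero phase, so
event timing is not shifted), with both configurable; ends are handled by
demeaning plus odd-reflection padding so constants pass through exactly.
Gaps of at most 3 samples are interpolated; longer gaps split the series
into independently filtered segments. `disc_average()` selects grid
points by haversine distance on a sphere of radius 6371 km and reports
the population (divide-by-n) standard deviation, matching how error bars
on disc-averaged satellite data are usually computed.

## Problem sizes

The shipped tests and the acceptance script use: 100–400-cell columns
(dz 0.5–4 m), 10–100-day integrations at dt = 150–3600 s, a 6 × 6
light × nutrient sweep of 20-day (tests) and 60-day (acceptance) box
runs, and hourly 20–40-day series for the filter checks — sizes chosen so
the whole suite illustrates every claim while remaining quick to run on a
laptop.

## Known limitations

* One nitrogen currency: no ammonium, no size-structured detritus, no
  multi-element stoichiometry.
* No horizontal dimension; upwelling is a prescribed velocity, not a
  dynamical response, and there is no interactive mixing closure.
* The Geider/temperature closures are documented package choices; they
  are structurally faithful to the cited model family but not asserted
  to be bit-identical to any operational code.
* Gridded I/O is delimited text; fields of realistic satellite size
  should be down-sampled before use.
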