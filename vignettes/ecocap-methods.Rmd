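---
title: "Model and methods: multispecies yield under an ecosystem cap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: multispecies yield under an ecosystem cap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ecocap)
```

`ecocap` is a deterministic, zero-dimensional (single well-mixed box)
multispecies simulator built to study one management question: can an
ecosystem-level cap on aggregate catch ever bind, once predation,
climate forcing, and the exploitation level of a key predator are
accounted for? This vignette documents the model equations, the
parameters that matter, the synthetic food web the package generates,
and the numerical choices behind both — including the places where the
design was genuinely open and we had to pick.

## State and time stepping

The ecosystem state holds numbers-at-age `N[g, a]` and weight-at-age
`W[g, a]` (kg) for age-structured groups (fish and endotherm top
predators) and biomass `B[g]` (t) for pools (plankton, benthos). Ages
are 1-based class indices; a class spans `years_per_age` calendar
years, so long-lived species fit in ~10 classes. The engine steps at
`dt = 1/12` yr by default (configurable). Equilibrium metrics — not
sub-monthly dynamics — are the target, so a monthly step is a
deliberate compromise: within-year seasonality of temperature is
resolved, and all within-year survival factors compound exactly
(`∏ e^(−Z·dt) = e^(−Z)`).

Annual events happen at year boundaries: recruitment enters age
class 1 at the reference entrant weight, and classes age. Annual
classes shift wholesale with the oldest class acting as a plus group
(`N_A' = N_{A−1} + N_A`). Multi-year classes graduate *fractionally* —
a fraction `1/years_per_age` of each class advances per year, the
exponential residence-time approximation familiar from
stage-structured models. We initially aged multi-year classes by
discrete shifts every `years_per_age` years, but that imprints
artificial cohort pulses with the class period on catches and biomass
(last-five-year catch CVs up to ~0.1 at calibration); fractional
graduation removes the pulses while preserving mean residence time,
the plus group, and exact conservation of numbers.

A related subtlety: graduating fish carry their *relative condition*
`W / W_ref` into the next class, not their absolute mass. With
absolute-mass carriage a fully-fed population sits permanently below
its reference weight schedule (each class starts at the previous
class's reference), which biases spawning biomass low by a few percent
and shifts the recruitment fixed point. With condition carriage the
fully-fed equilibrium is exactly `W_ref` at every census, and
food-driven condition anomalies still propagate through the age
structure — which is what the food-web experiments need.

## Temperature enters in three distinct ways

1. **Consumption scaling** `f(T)`: the unimodal bioenergetic response
   used in fish bioenergetics (Kitchell/Thornton–Lessem family).
   With `V = (T_max − T)/(T_max − T_opt)`,
   `Z = ln(Qc)(T_max − T_opt)`, `Y = ln(Qc)(T_max − T_opt + 2)`,
   `X = Z²(1 + √(1 + 40/Y))²/400`, the scalar is `V^X e^{X(1−V)}`,
   exactly 1 at `T_opt` and 0 at `T_max`. Endotherms bypass it —
   direct bioenergetic effects of water temperature on birds and
   mammals are not represented.
2. **Habitat suitability** `σ(T)`: a trapezoid over temperature
   (0 outside `[T0, T3]`, 1 on `[T1, T2]`, linear shoulders) that
   multiplies foraging demand. In a spatially explicit model thermal
   niches restrict distributions; in a 0-D box the same mechanism
   survives only as a foraging-exposure multiplier, which is the one
   real structural collapse in this design.
3. **Spawning window**: recruitment is gated by a trapezoid that is 1
   inside `[T_lo, T_hi]` and tapers linearly to 0 over `τ` (default
   1 °C; `τ = 0` gives a hard gate — edge behaviour was unspecified,
   a linear taper is the least surprising choice). A stenothermic
   spawner whose spawning-day temperature leaves the tapered window
   recruits nothing that year.

## Trophic interactions

Predation uses a multispecies Holling type-II response. Demand per
predator age class is `D = Cmax · f(T) · σ(T) · W · N · dt` (t). The
prey field is `Φ = Σ_p a[pred, age, p] · B_p`, with availability
`a ∈ [0, 1]` and total prey biomass `B_p`; intake is
`D · φ/(1 + φ)` with `φ = Φ/H` and a single half-saturation biomass
`H` per predator, allocated across prey in proportion to `a · B_p`.
The response form is a modelling decision, not an empirical claim: it
is the simplest form that produces diet shifts as prey fields change.
Removal from any one prey is capped at 90% of its biomass per step
with proportional rescaling of all flows onto it — positivity without
implicit solvers.

Flows convert to prey mortality as a uniform instantaneous rate,
`M2 = consumed / (B · dt)`, distributed over prey ages in proportion
to biomass-at-age. Two consequences worth knowing: (i) at large
`M2·dt` the exponential survival removes slightly less biomass than
the predators were credited with (the linear-vs-exponential mismatch
is < 2% at the default step and cap); (ii) because the diet matrix has
no prey-age dimension, a predator cannot prefer adults — when heavy
fishing removes a prey's predators, juvenile biomass can boom and any
predator "of" that prey shares the boom. The synthetic web's
groundfish-reliant endotherm is therefore anchored on adult-dominated
stocks (see below).

Groups whose availability row is all zero (no diet links) are treated
as *externally fed*: zero demand, ration `ρ = 1`. This keeps
single-species and decoupled configurations exactly on their
closed-form equilibria, which the test suite exploits heavily.

Weight relaxes toward the ration-scaled reference,
`W' = W + κ(ρ·W_ref − W)·dt` with `κ = 1` yr⁻¹ — sustained full
rations hold `W_ref`, sustained half rations converge to `0.5·W_ref`.
`κ` sets how fast food limitation becomes biomass; 1 yr⁻¹ makes
condition respond within a year without oscillation.

## Recruitment

Beverton–Holt in steepness form:
`R = 4hR0·SSB / (S0(1−h) + SSB(5h−1))`, times the spawning gate.
`R0` is unfished recruitment, `h ∈ (0.2, 1]` steepness (`h = 1` gives
constant recruitment — used in tests to expose the Baranov
yield-per-recruit closed form), and `S0` the unfished spawning
biomass anchor. SSB is censused on the spawning day (default day 90),
so the default `S0` is the analytic unfished SSB *discounted by the
background mortality elapsed before spawning*; without that
consistency the unfished fixed point misses by a few percent.
Endotherms reproduce as `R = R0 · min(1, ρ̄)` with `ρ̄` the
numbers-weighted annual mean ration — prey-driven body condition, not
SSB, controls their trajectory.

Pools are logistic, `B' = B + r·s·B(1 − B/K)·dt − losses`, floored at
zero; `s` is the productivity scalar through which a warm regime
halves plankton productivity. The exported `pool_update()` is the
plain Euler form; inside the engine the update is sub-stepped so that
`r·s·dt ≤ 0.2` per sub-step, because fast pools (diatom-like, `r ≈ 25`
yr⁻¹) are unstable under monthly Euler steps (the classic logistic-map
oscillation) and the sub-stepping keeps them on the smooth path.

## Forcing

A climate regime is a 365-value daily temperature climatology looped
year after year — zero interannual variance by construction, so
end-of-run means are genuine equilibria — plus per-group productivity
scalars. The projected regime is built by the same pipeline one would
apply to real model output: delta bias correction
`x′ = x̄_hind + (x_proj − x̄_hist)` applied at daily resolution,
collapse of the multi-year corrected series to one daily climatology,
and halving of plankton productivity. The synthetic "historical"
climatology is a sinusoid (mean 7 °C, amplitude 4 °C — a plausible
subarctic shelf cycle) and the synthetic projection adds a uniform
warming `warming_delta` (default +2.5 °C) plus a model bias that the
delta correction must remove exactly; alternating ±0.3 °C interannual
offsets are constructed to cancel in the climatology, which the tests
assert.

## Simulation protocol and experiment

Runs last 80 years: a 30-year burn-in under calibration fishing
(focal stocks at ¼F_OFL; other fished groups at ¼M) and historical
forcing, then an abrupt switch to the scenario policy and regime for
50 years. All reported quantities are means (and CVs) over the final
five years. "Equilibrium" is operational — no convergence criterion is
imposed, and divergence detection is by non-finite state only.

Step 1 profiles each focal stock over 13 evenly spaced multipliers
{0, 1/3, …, 4} of its F_OFL (stocks without an F_OFL profile over
multipliers of M). Even spacing with both endpoints is our reading of
"13 values between 0 and 4×F_OFL"; the multiplier-0 run doubles as
the unfished baseline and ×4 results are part of the design. `F_MSY`
is the grid argmax of last-five-year mean catch, ties broken toward
the smallest F, with a boundary flag when the argmax sits at 4×F_OFL.
Step 2 multiplies the `MF_MSY` vector by the same 13 multipliers under
four scenarios (climate × key-predator policy); under the
underexploited policy the predator's F stays at ¼F_OFL at *every*
multiplier, including 0. Burn-ins always use calibration fishing — the
alternative (burn-in at scenario fishing) was considered and rejected
because it would confound initial-condition effects with scenario
effects.

## Evaluation metrics

* **Cap attainment**: aggregate last-five-year mean catch over
  cap-countable focal stocks (the halibut-like stock is fished but
  excluded), attained when ≥ cap (boundary inclusive, by convention).
* **B35% counts**: stocks with SSB below 35% of unfished SSB. The
  default baseline is the *same-scenario* multiplier-0 run, which
  isolates fishing effects from climate effects (every stock is at
  its own baseline at multiplier 0, so counts start at 0 and rise
  monotonically). The alternative — the historical unfished run — is a
  config switch (`b35_baseline = "historical"`) and is the right
  baseline when the question is "how depleted is this stock relative
  to the world before warming?", e.g. for the cod-like collapse,
  which is invisible against a warm baseline that has already
  collapsed.
* **Depletion**: SSB(F)/SSB(0); values slightly above 1 are possible
  through predation release.
* **Indirect effects**: for each forage group, the % change in total
  biomass of its predators versus the multiplier-0 run (link sets
  from availability > 0); symmetrically for top predators and their
  prey.
* **Realised diet**: proportions of summed consumption flows over a
  year window.

## The synthetic food web

`generate_goa_like_web()` builds the 26-group study system: 12 focal
groundfish (11 with assessment F_OFL values 0.06–0.51 plus a
halibut-like stock with base M = 0.2 yr⁻¹ that does not count toward
the cap), 5 forage fish, diatom/copepod/euphausiid pools plus benthos,
and 5 endotherm predators. Structure the analysis assumes, built in
deliberately:

* the arrowtooth-like predator has dominant availability on
  pollock-like and cod-like prey (`predator_strength` scales this
  link; 0 decouples it), so top-down control is present;
* the cod-like stock spawns in a narrow window (2–6 °C, τ = 1 °C)
  that is open on the historical spawning day (~5.9 °C) and closed
  under +2.5 °C warming (~8.4 °C > 7 °C) — warm-regime recruitment
  failure is engineered via the stated mechanism, not fitted to data;
* the sea-lion-like endotherm relies on adult-dominated groundfish
  (arrowtooth, cod, sablefish, flatfish) with only marginal
  availability on pollock, for the prey-age reason explained above;
  the dolphin-like group relies on forage fish and benefits from
  groundfish removals.

Life-history values (ages, growth, M0, steepness, thermal windows)
are fixed plausible choices at subarctic-shelf magnitudes, not
estimates; all are config-overridable and serialized with the config.
Biomass scale was set once so that the default web's aggregate
cap-countable yield stays below the 800,000 t cap across the whole
multiplier grid — the regime the cap-evaluation question presumes —
which is a pure rescaling: saturation, M2 and F are all ratio-based,
so relative dynamics are unchanged.

Initialisation works in two passes. An analytic pass estimates
predation mortality and rations once at the target biomasses and
anchors `R0`, `S0`, `H` (set to ¼ of the availability-weighted prey
field, placing unfished rations near 0.8) and the age structures
self-consistently. A 50-year unfished spin-up under historical forcing
then replaces the initial state with the model's own settled
equilibrium. The spin-up is what makes the generated web start on its
attractor: an 80-year unfished run stays within ±1% of its initial
biomass for every group, and calibration-fished runs have last-five-
year catch CVs ≤ 0.002.

## What the synthetic web does and does not show

Passing tests on this web demonstrate that the *machinery* behaves:
conservation identities hold, decoupled stocks sit on closed-form
equilibria, yield curves match yield-per-recruit oracles, and the
qualitative food-web responses (predator release of forage fish,
foregone yield under predator underexploitation, warm-regime
recruitment collapse, monotone rise of overfished-stock counts) emerge
from the stated mechanisms. They do not validate the model against
any real ecosystem: there is no space, no fleet structure, no
nutrient cycling, availabilities are invented, and the biomass scale
is set by construction. Quantities like "F_MSY of the arrowtooth-like
stock" describe this synthetic system only.

## Numerical choices, degenerate inputs, problem sizes

* Monthly step; pools sub-stepped to `r·s·dt ≤ 0.2`.
* Per-prey removal capped at 90% per step, flows rescaled
  proportionally.
* `CV = sd/mean`, defined 0 when the mean is 0; zero-SSB recruitment
  is 0; zero unfished SSB excludes a stock from B35% counting with a
  warning; an all-zero yield curve selects `F_MSY = 0` by tie-break.
* Configs serialize to YAML at full double precision
  (`write∘read = identity`, byte-stable digests); unknown keys are
  rejected with their location.
* Default problem sizes: 26 groups × ≤10 age classes, 80-year runs
  (~1 s each), 156-run Step 1 (~2.5 min), 52-run Step 2 (~1 min).
  The test suite uses the same sizes for the directional checks and
  smaller decoupled webs (5–10 classes, 8–60-year runs) for the
  oracle and property tests.

## Known limitations

The single box removes distribution shifts, so the thermal-niche
multiplier understates (or misstates) spatial climate effects. The
shared-H type-II response cannot represent prey switching or
predator-specific saturation. Uniform-over-age M2 ignores
size-structured predation within a prey group. Endotherm demography
(condition-scaled recruitment, no SSB feedback) is the simplest form
consistent with prey-driven biomass change. Fishing is a
time-invariant F with knife-edge selectivity — no harvest control
rules, discards, or fleet behaviour. All of these are scope
boundaries, not bugs; the experiment layer is agnostic to the
dynamics engine behind the module interfaces.
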