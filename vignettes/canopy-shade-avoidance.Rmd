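---
title: "Simulating hyponasty and competition in rosette canopies"
author: "canopyfsp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating hyponasty and competition in rosette canopies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the simulator addresses

Plants in dense stands raise their leaves (hyponasty) and elongate their
petioles when they sense neighbours — the shade avoidance syndrome (SAS).
These responses help the individual but open the canopy, letting light
reach the soil where invading competitors (weeds, in a crop setting) can
establish. `canopyfsp` is a functional–structural plant (FSP) simulator
built to ask: how does the *rate* of shade-induced hyponasty in an
Arabidopsis-like monoculture change light penetration to the soil, and how
does that feed back on the growth of competitors that invade the stand?

The package simulates three scenarios over 44 daily time steps on a 10 × 10
canopy grid at 2.5 cm spacing (1,600 plants m⁻²): (1) the monoculture
alone, (2) the monoculture invaded by 16 competitors with *weak* SAS (no
hyponasty, slow petiole elongation), and (3) the same invasion by
competitors with *strong* SAS (hyponasty at 16°/day, full elongation).
Competitors germinate 3 days after the canopy plants. Canopy hyponasty
rate is the experimental variable, swept over 1, 5, 10, 15 and 20°/day.

## Model structure

### Architecture

A plant is a rosette: an ordered collection of leaves, each a straight
petiole bearing a planar elliptical lamina (length:width = 2:1). Leaves
appear on a plastochron clock (one every 1.5 days by default, to a cap of
25), at 137.5° azimuthal steps from a per-plant random first azimuth, and
at an initial petiole elevation of 30°.

One architectural choice deserves emphasis. The petiole elevation is the
hyponasty state variable, but the lamina is *not* held coplanar with the
petiole: it is displayed at the petiole elevation minus a fixed 25°
backward bend (floored at horizontal). This mirrors how hyponastic
rosettes actually hold their blades — the petiole rises steeply while the
blade stays displayed flatter — and it is load-bearing for the biology the
simulator is meant to express. In development we measured that with
strictly coplanar blades, an erect competitor's laminas absorb essentially
zero PAR per unit area deep in the canopy (a vertical blade presents
almost no cross-section to the predominantly downward light), so upward
escape could never pay off and the strong-SAS phenotype always lost to the
weak one. With the bend, an erect leaf trades a modest display penalty
(cos of the blade elevation) for height, and the canopy-opening effect of
hyponasty arises mostly from *footprint shrink*: erect long petioles pull
the blades inward over the plant axis, uncovering the ground between
plants.

### Radiation

Light transport is forward Monte-Carlo ray tracing in three bands — PAR,
red (R) and far-red (FR) — each band traced independently with its own
optical coefficients. The source models a growth chamber: 220 µmol m⁻² s⁻¹
PAR on an unobstructed horizontal plane at R:FR = 2.3, with a
cosine-weighted ("overcast-diffuse") angular distribution; a vertical-only
mode is retained because it admits an exact brute-force oracle. Rays
scatter off laminas Lambertian-ly (reflect or transmit, chosen by the
band's coefficients) to a depth of 5 bounces with Russian-roulette
termination below 10⁻³ relative weight; petioles are opaque. Default leaf
optics (PAR 0.85/0.075/0.075, R 0.90/0.05/0.05, FR 0.10/0.45/0.45 for
absorptance/reflectance/transmittance) follow the usual leaf-spectrum
shape — strong red absorption, strong far-red scattering — so the R:FR
ratio collapses below the 0.5 response threshold under one to two leaf
layers. These optics are calibration constants of the simulator, not
measurements.

The lateral boundary is periodic: a ray leaving the side of the domain
re-enters on the opposite side, which makes an empty scene return exactly
the source intensity everywhere and represents the stand as if repeated —
appropriate because all reported metrics exclude the plot edges anyway
(the "middle 16" canopy plants and "middle 4" competitors). Soil PAR is
tallied on virtual soil tiles covering the 100 cm² under the middle 16
canopy plants.

Tip R:FR sensing does not rely on forward-ray tallies on the tiny sensor
discs, which would starve deep in a closed canopy. Instead each lamina tip
estimates its downward R and FR fluence by adjoint sampling: 32
cosine-weighted upward rays accumulate the product of lamina
transmittances to the sky (petiole crossings are opaque; the sensing
leaf's own organs are excluded; the sensor never occludes). In an empty
scene this reads the source ratio exactly; under n identical layers it
reads the closed-form `2.3 · (τ_R/τ_FR)ⁿ`. It neglects scattered
enrichment at the sensor point, which the closed-form test oracles also
neglect; the forward pass still transports scattered light for all energy
quantities.

### Responses and growth

Each daily step runs in a fixed order: leaf initiation → radiation →
signal evaluation → hyponasty and elongation responses → assimilation →
allocation → organ growth → metrics. A leaf's response is triggered by
virtual touching (its lamina within 2 mm of another plant's lamina) OR by
tip R:FR strictly below 0.5 — no other pathway. Hyponasty adds the
phenotype's rate (°/day) to the petiole elevation, capped at 80°,
irreversibly. Triggered leaves also elongate: the petiole length gained
per unit of allocated mass is multiplied by `1 + elongation_multiplier`
(default 1.0 for canopy and strong-SAS plants, 0.15 for weak-SAS), and the
leaf's petiole sink is boosted (multiplier `1 + 4 ·
elongation_multiplier`), rerouting carbon towards elongation at the
expense of lamina growth — the classic SAS resource shift. Without this
reallocation, petioles in the simulator stay a few millimetres long and no
angle strategy has any geometric consequence.

Photosynthesis is a linear light-use efficiency: daily carbon (mg) = LUE ×
total absorbed PAR integrated over the 9 h photoperiod (default LUE
1.8 g per mol photons, in the range implied by quantum-yield arithmetic).
Allocation is sink-regulated: each organ's demand is its potential final
mass (lamina 10 mg, petiole 8 mg at mature ranks, ramped down for the
first ranks) times the increment of a symmetric Beta(3,3) CDF over a
12-day expansion window; supply is split proportionally to demand and
never exceeds it, with any surplus held in a per-plant carbon pool.
Conservation is exact to floating-point rounding, and a seed reserve of
0.4 mg released at germination bootstraps growth. The growth forms are
deliberately simple stand-ins for an empirically fitted rosette model: the
paper trail for the real functions lives in prior work that this package
does not reproduce; what matters here is that the light → carbon →
architecture causality is preserved.

### Calibration

The quantitative defaults were calibrated jointly, once, against two
anchors, and then frozen: (i) a 1°/day monoculture must close its canopy
within about 30 days (central soil PAR below 60 µmol m⁻² s⁻¹ at day 30 —
in the default configuration it reaches ~40 with closure around day 23),
and (ii) organ proportions at high density should be petiole-dominated
(petiole length of the order of, or exceeding, lamina length), as
high-density rosettes are. The knobs involved — LUE, SLA (25 mm²/mg),
plastochron, organ potentials, petiole linear density (0.2 mg/mm),
elongation multiplier and petiole sink boost — are documented in
`growth_params()` and `sas_params()` and all overridable.

## What the simulations show

With the default calibration the simulator reproduces the directional
results of the study it models, and the test suite asserts all of them:

- Day-30 central soil PAR increases monotonically with the canopy
  hyponasty rate; slow-hyponasty canopies (1, 5, 10°/day) hold it below
  60 µmol m⁻² s⁻¹.
- Weak-SAS competitor biomass at day 44 is higher under fast-hyponasty
  canopies (15, 20°/day) than under slow ones — more light reaches the
  soil where the flat-growing competitor lives.
- Canopy biomass shows the opposite trend: fast hyponasty costs the
  monoculture.
- A strong-SAS competitor outgrows a weak-SAS one under the same canopy:
  its erect, elongating leaves climb towards brighter strata, which pays
  off because blades stay displayed flatter than petioles (see above).

## Numerical choices and degenerate inputs

- Monte-Carlo results are seed-reproducible bit-for-bit; per-stand and
  per-day RNG substreams are derived deterministically from one master
  seed (PCG32 in the C++ core, independent streams per band).
- Per-band energy conservation (emitted = absorbed + soil + escaped) is
  exact per ray except for Russian roulette, whose imbalance is tracked
  with a per-ray variance estimate; tests assert the gap stays within 3
  standard errors.
- Zero-dimension laminas become empty polygons and are skipped (and
  counted) by the tracer, never errors. A tip receiving zero far-red flux
  reads `+Inf` (never a division error) and therefore does not trigger.
- The R:FR threshold is a strict inequality: a tip at exactly 0.5 does not
  trigger. Touch is neighbour-only by default (same-plant contact
  configurable) with a 2 mm tolerance on true 3D lamina–lamina distance.
- Ties in central-plant selection break deterministically by x then y.
- Rosettes sit 2 mm above the soil plane so that flat leaves never
  z-fight with the soil tiles.

## Problem sizes

Full-fidelity runs (10 stands per scenario and rate, 200k rays/day) are
what `run_scenario()` defaults target. The shipped test suite and the
acceptance script use reduced sizes chosen as the smallest that keep every
directional comparison well clear of Monte-Carlo noise: 2–3 stands per
condition, 10–20k rays per band per day, 16 sensing directions per tip,
and sweeps to day 31 where only day-30 light is needed. The rate-ordering
test works on per-stand paired differences (shared seeds across rates)
with an explicit 2-standard-error Monte-Carlo slack.

## What passing tests do and do not show

The synthetic stands emulate the geometry, light regime and phenotype
contrasts of a growth-chamber competition experiment; they do not emulate
real Arabidopsis physiology. Organ growth functions are stand-ins;
reproduction, senescence, water and nutrients, leaf-size shade plasticity
and the hormonal mechanism of SAS are all absent; hyponasty here is
irreversible although the real response partially fades. Passing tests
therefore show that the *model* expresses the studied causal chain —
hyponasty rate → canopy openness → competitor light → competitor biomass —
under its own calibrated conditions, not that it predicts any particular
experimental value.

## Known limitations

- The blade bend (25°) is a single architectural constant; real blade
  display varies with rank, age and light.
- The adjoint tip sensor ignores scattered FR enrichment from below;
  under the default optics this biases tip R:FR slightly upward in very
  dense canopies (conservative for triggering).
- The periodic lateral boundary slightly over-shades edge plants relative
  to an open-sided plot; central-region metrics are unaffected by design.
- Competitor placement interpolates a centered symmetric arrangement
  between canopy plants; the exact experimental placement map is not
  machine-readable, so symmetry is the rule.
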