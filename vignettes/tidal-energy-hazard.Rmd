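---
title: "Partitioning tidal inflation energy into safe and hazardous fractions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning tidal inflation energy into safe and hazardous fractions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventergy)
```

## The model

Lung-protective ventilation tries to avoid repeatedly exceeding the strain
a lung can tolerate. Pressure limits alone (plateau pressure `Ps`, driving
pressure `DP = Ps − PEEP`) do not capture dose: injury requires the
expenditure of energy, and per-minute energy delivery ("mechanical power")
mixes frequency with per-cycle energy. ventergy implements a middle path:
partition the conserved (elastic) energy of each passive inflation at a
*threshold elastic pressure* `Pt` into an infra-threshold fraction taken to
be safe on average and a supra-threshold fraction taken to be hazardous,
then express damaging power as frequency × supra-threshold energy per
cycle.

The mechanical model is a passive single compartment with linear
compliance `C`: during inflation the elastic pressure rises linearly with
inflated volume from `PEEP` to `Ps = VT/C + PEEP`. Chest-wall elastance is
deliberately ignored — all pressures are airway (circuit) pressures
referenced to atmosphere, used as surrogates for the distending stress —
and only inspiration is modelled: the energy accounting is inflation-only.
Resistive pressure is treated as dissipated and never enters the elastic
energy.

Two accountings of per-cycle elastic energy coexist in clinical reasoning,
and both are carried everywhere in the package:

* **drive**: only the tidal area, `W_drive = ½·DP·VT = VT²/(2C)`;
* **elastic**: the whole conserved area including the PEEP block,
  `W_elastic = ½·(Ps + PEEP)·VT = VT²/(2C) + VT·PEEP`.

One widely printed shorthand writes the drive energy as `½·Ps·VT`; that
expression equals `VT²/(2C)` only when PEEP = 0, so ventergy uses
`½·DP·VT` throughout, which is consistent with the tidal area geometry and
with the drive hazard ratio below.

Given `Pt`, the hazardous fractions are ratios of P–V areas:

$$\mathrm{HR}_{drive} = \frac{(2\,DP + P_t - P_s)(P_s - P_t)}{DP^2}
  = 1 - \left(\frac{P_t - \mathrm{PEEP}}{DP}\right)^2,
  \qquad
  \mathrm{HR}_{elastic} = \frac{P_s^2 - P_t^2}{P_s^2 - \mathrm{PEEP}^2},$$

with safety ratios `SR = 1 − HR`. Neither variant is privileged as the
headline metric — which energy "counts" is a modelling stance, not a
settled question — so every result reports both. Damaging power is
`f · HR · W` for each variant; all powers are exactly linear in frequency.

`hr_drive()` evaluates the difference-of-squares form
`(DP² − (Pt − PEEP)²)/DP²` rather than the product form: the two are
algebraically identical, but the former yields the boundary identities
(`Pt = Ps ⇒ HR = 0`, `Pt = PEEP ⇒ HR = 1`) and the zero-PEEP collapse
`HR_drive = HR_elastic` exactly in floating point, not just to rounding.

## Parameters, units, defaults

| parameter | meaning | unit | constraint / default |
|---|---|---|---|
| `ps` | plateau (static end-inspiratory elastic) pressure | cmH2O | `> peep`; derivable from `vt/c + peep` |
| `peep` | end-expiratory pressure | cmH2O | `>= 0` |
| `vt` | tidal volume | L | `> 0` |
| `c` | compliance | L/cmH2O | `> 0`; derivable from `vt/(ps − peep)` |
| `f` | frequency | breaths/min | `> 0` |
| `pt` | threshold elastic pressure | cmH2O | referenced to atmosphere |

Energies are kept internally in cmH2O·L (a pure P×V area) and reported
also in joules (1 cmH2O·L = 0.0980665 J), since no single unit convention
dominates bedside practice. Exactly one of `ps` and `c` may be omitted;
when both are given they must agree (`ps = vt/c + peep`) to a relative
1e-9 — disagreement means the inputs describe two different lungs and is an
error, not something to average away.

The threshold itself is unknown and arguably unknowable per patient; a
pragmatic anchor is the customary safe upper bounds `Ps = 30`, `DP = 15`
cmH2O, suggesting `Pt ≲ 15 + PEEP`. Thresholds outside `[PEEP, Ps]` are
clamped by default (the supra-threshold fraction saturates at 1 or 0,
which is what the area geometry says); `policy = "strict"` turns them into
errors for pipelines that prefer to be told.

## Inverse targets

If the current pattern's hazard ratio is higher than intended,
`prescribe_targets()` solves for the setting that achieves a requested
ratio `h` (safety requests are converted through the complement
`HR = 1 − SR`):

* **drive** variant: solve the drive formula for `DP` with `Ps` and `Pt`
  held fixed. The quadratic's physical root is
  `Target DP = (1 − √(1−h))/h · (Ps − Pt)`, which ventergy evaluates in
  the cancellation-free equivalent `(Ps − Pt)/(1 + √(1−h))` — continuous
  through `h = 0`, where it takes the analytic limit `(Ps − Pt)/2`.
* **elastic** variant: solve for the plateau with `PEEP` and `Pt` fixed,
  `Target Ps = √((Pt² − h·PEEP²)/(1 − h))`; `h = 1` leaves the target
  unbounded and is an error.

Tidal volume then rescales linearly with the solved pressure:
`Target VT = (Target DP/DP)·VT = ((Target Ps − PEEP)/DP)·VT`. The
`held_fixed` column records which knobs each route assumes immovable,
because the assumption matters: in the drive route the implied PEEP
(`Ps − Target DP`) typically rises above `Pt`, i.e. the solved point lies
where the area algebra extrapolates beyond its geometric domain. The
round-trip invariant — re-inserting the target into its formula recovers
`h`, reported as `achieved_ratio` — therefore uses the raw printed formula,
and holds to better than 1e-9 across `h ∈ [1e-6, 1]` in the test suite.
Frequency is never re-tuned: compensating minute ventilation after a VT
change is a clinical decision with no closed-form rule here.

## Regional thresholds

The stress that strains tissue is transpulmonary pressure, which at equal
airway pressure varies with gravitational height; regional damage
thresholds expressed on the airway scale vary correspondingly.
Non-dependent regions sit at higher transpulmonary pressure, so their
local `Pt` is *lower* (more vulnerable to additional stretch); dependent
regions the converse. ventergy models this with the simplest form
consistent with a uniform pleural gradient — linear in normalised height
`x` (0 = most dependent, 1 = most non-dependent) and centred on the
whole-lung average:

$$P_{t,local}(x) = P_{t,avg} + \mathrm{span}\cdot(\tfrac12 - x),$$

where `span` is the total pleural-pressure difference across the lung.
This linear substitution is this package's own stand-in parameterisation,
chosen where no published closed form was adopted; regional vulnerability
enters *only* through the threshold — the same whole-lung hazard formulas
are evaluated at each local `Pt` (clamped mode, since extreme positions
may push the local threshold past `Ps` or below `PEEP`). The default spans
(supine 7.5, prone 3.0 cmH2O) are illustrative, not measured values; they
encode the one qualitative claim the model insists on, that prone
positioning flattens the gradient and therefore strictly narrows the
spread of regional vulnerability. Discretisation defaults to 11 evenly
spaced positions; position ½ reproduces the whole-lung result exactly.

## Waveform simulation

`simulate_cycle()` integrates the equation of motion
`P_aw = R·flow + V/C + PEEP` on a uniform time grid (default
`n_steps = 2000`, minimum 100) over one inspiration. Built-in profiles:
constant flow `VT/Ti` and a decelerating linear ramp from `2·VT/Ti` to
zero; custom profiles are sampled arrays, interpolated onto the grid and
rescaled so the integral of flow equals `VT` exactly. Because the elastic
pressure is a linear function of volume, the trapezoid rule integrates
`∫P_el dV` exactly up to rounding on any volume grid — which is precisely
why the simulated cumulative energy reproduces `½(Ps+PEEP)·VT` for *every*
flow profile (the waveform-invariance property) to ~1e-15 rather than
merely to a discretisation tolerance. What the waveform does change is the
pace of delivery (intracycle power `P_el·flow`) and `time_above_threshold()`,
the duration spent above `Pt`; threshold crossings are refined by linear
interpolation between grid points, so crossing times converge
quadratically with the grid. Resistance `R` (default 10 cmH2O·s/L) shifts
only the airway pressure, never the elastic energy.

## Verification design

All closed forms are checked against `oracle_hr()`, a numeric P–V area
integrator that shares no algebra with them: it locates the threshold
crossing on the elastic line by root finding (`uniroot`), then integrates
the supra-threshold and total areas by the trapezoid rule (default 1e5
panels per side; compliance cancels in the ratio). Locating the crossing
first matters — integrating a discontinuous indicator on a fixed grid
would limit accuracy to O(1/n), while the two-segment integral of the
(linear) integrand is exact, so closed form and oracle agree to machine
precision, far inside the 1e-9 bound the tests assert.

The property suites run on batches from `generate_fixtures()`: seeded
scenarios with PEEP uniform on 0–15 cmH2O, DP on 5–25 cmH2O, `Pt` uniform
on `[PEEP, Ps]`, VT on 0.2–0.8 L and f on 10–35 breaths/min — a grid
spanning lung-protective through moderately injurious adult settings.
These synthetic scenarios are internally consistent by construction; real
measurements are not. The generator does not emulate nonlinear compliance,
intra-breath recruitment, spontaneous effort, chest-wall stiffness,
breath-to-breath variability or measurement noise, so green tests certify
the calculator's mathematics, not the fidelity of any particular bedside
estimate fed into it. Verification sizes: 10,000 random triples for the
oracle-equivalence sweep, 100 scenarios × a 101-point ratio grid for the
round trips, 20 random flow profiles for waveform invariance — each chosen
to exercise the whole parameter box while keeping the full suite around
half a minute.

## Limitations

The model is deliberately conceptual. It ignores chest-wall elastance,
viscoelastic losses, stress focusing by tissue heterogeneity, alveolar
micro-mechanics and vascular cofactors; thresholds are assigned, not
identified from injury data; and airway pressures correlate with, but do
not equal, tissue stress. The package computes the consequences of the
model's assumptions precisely — it does not validate the assumptions.

```{r example}
ventilation_scenarios(ps = 25, peep = 5, vt = 0.5, f = 20, pt = 20) |>
  partition_energy() |>
  glance()
```
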