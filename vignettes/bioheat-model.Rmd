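---
title: "A multi-segment bioheat model for asymmetric high-temperature exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-segment bioheat model for asymmetric high-temperature exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioheatr)
```

## The model

`bioheatr` simulates whole-body human heat transfer under angularly
non-uniform, potentially very hot environments. The body is fifteen
cylindrical segments (head, chest, abdomen and six paired limb
segments); each segment carries a core node, an arterial node, a venous
node and **four angular skin sectors** (anterior, exterior, posterior,
inferior), for 105 temperature nodes in total. The sector resolution is
what lets the model answer questions a one-skin-node model cannot: how
much hotter the wall-facing side of an arm runs when a worker stands
next to a furnace wall or burning facade.

Two interacting systems are solved together:

* the **passive system** — energy balances on every node: metabolic
  heat, core-skin conduction, tangential conduction around the sector
  ring, blood advection through an artery/vein tree rooted at the
  chest, and per-sector boundary exchange (convection, evaporation,
  radiation, plus respiratory loss at the chest core);
* the **active system** — vasodilation/vasoconstriction of skin blood
  flow, sweating and shivering, driven by the deviation of the head
  core temperature from its 36.9 °C reference and by skin error signals
  `Err_i = T_sk,mean,i - T_sk0,i` aggregated with the per-segment
  sensitivity weights (`Wrms`, `Clds`).

Three high-temperature extensions sit on top of the classical
controller:

* a **metabolic multiplier** `max(1, 1 + 0.13 (T_cr - 39))`, active
  only when the ambient temperature is at or above 39 °C;
* **dehydration bookkeeping**: cumulative sweat mass as a percentage
  `D` of a 74.30 kg reference body mass, reported together with the
  heart-rate increment `dHR = 4.75 D`;
* a **dehydration-modified sweating controller**
  `Sweat = (0.2898 - 0.068 D)(T_head - 37 - 0.06 D) + 0.03364 Wrms - Clds`
  (kg/h, clamped at zero, sensitivity floored at zero near
  `D = 4.26 %`): each percent of water loss raises the sweating onset
  threshold by 0.06 °C and blunts the sensitivity by 0.068 kg/(h·°C).

## Blood network and energy bookkeeping

Arterial flow is accumulated leaf-to-root over the tree
(chest→head, chest→arm chains, chest→abdomen→leg chains), so every
branch point conserves mass; venous return mirrors the arterial side,
and the heart closes the loop (the chest artery is fed at the central
venous temperature). Per-segment core perfusion defaults to a resting
core blood flow of 277 L/h distributed in proportion to basal core
metabolic rate; skin perfusion is the controller output, split over
sectors by the temperature-excess redistribution rule (hotter sectors
receive more flow, the segment total is conserved).

One bookkeeping subtlety matters enough to state explicitly. Perfusing
blood enters a core at the arterial temperature and leaves it at the
core temperature; the skin-bound share then deposits
`w_sec (T_cr - T_sk)` in its sector and returns to the local vein **at
skin temperature**, while the core-bound share returns at core
temperature. Writing the core balance with both the full through-flow
discharge *and* a separate skin-perfusion loss double-counts the same
enthalpy and leaks energy (a few hundred watts on realistic states).
The package uses the conservative stream form throughout; with all
boundary exchange and metabolism disabled, the total enthalpy
`sum(C T)` is conserved to round-off over hours of simulation (the
fixed-step Runge–Kutta scheme preserves linear invariants exactly),
and the test suite asserts a drift below 1 J per simulated hour.

## Boundary exchange

Per sector `i` with area `A/4`:

* convection `CON = (A/4) h_c (T_sk - T_air,i)`;
* evaporation `EVA = (A/4) h_e (w P_sat(T_sk) - P_air)`, floored at
  zero. Skin vapor pressure is the wettedness-weighted Antoine
  saturation pressure; wettedness is the ratio of demanded sweat
  evaporation (latent heat 2430 kJ/kg) to the sector's evaporative
  capacity, clamped between the insensible minimum 0.06 and full
  wetness 1;
* radiation in two parts: a linearised exchange
  `(A/4) h_r (T_sk - T_mrt)` with the enclosure, plus, for each planar
  radiant source seen by the sector, the fourth-power term
  `(A/4) sigma eps F_vf ((T_sk + 273.15)^4 - (T_r + 273.15)^4)`.

View factors from a sector (treated as a differential patch at the
segment's mid-height) to a vertical rectangular panel are computed
analytically by signed additivity of the classical corner formula, so
subdividing a panel and summing reproduces the whole-panel value to
machine precision; the test suite checks the values against a
brute-force double-quadrature oracle to 1e-4. A panel **displaces its
solid angle from the enclosure term**: the mean-radiant exchange acts
on the residual view factor `1 - sum(F_panel)`. Without this, a wall
held at the ambient temperature would spuriously cool the sector facing
it (it would radiate to the wall and to the full enclosure at once) —
the warm-wall fixture's unheated first stage is the degenerate case
that motivates the choice.

Clothing is a per-segment serial resistance: dry fluxes are scaled by
`1 / (1 + I_cl (h_c + h_r))` and evaporative fluxes by
`1 / (1 + R_ecl h_e)`; bare segments pass through unchanged.

## Parameters and defaults

Passive constants (areas, metabolic rates, capacitances, core-skin
conductances, basal/min/max skin blood flow) are the standard-body
values tabulated in `segment_table()`; paired limbs replicate the
per-type row. Set points and the sweating/shivering/sensitivity
distribution coefficients are in `thermoreg_table()`; the per-side
coefficients sum to ≈1 over the fifteen segments, which is the reading
under which the distributions are well-formed (interpreting the paired
rows as two-side sums would leave the columns summing to ≈0.78).

Quantities the source tables do not fix are explicit, overridable
defaults:

* **geometry**: canonical anthropometric segment lengths and standing
  mid-heights; skin-shell radius `r = A / (2 pi L_n)`, thickness 1 mm,
  conductivity 0.47 W/(m·K), emissivity 0.95. The tangential
  conduction coefficient of the sector ring is
  `K_sk L_n th_sk / r^2` with a periodic central second difference over
  the four sectors (`dtheta = pi/2`);
* **transfer coefficients**: still-air `h_c = 3.0`, `h_r = 4.7`
  W/(m²K), `h_e = 16.5 h_c` W/(m²kPa) by the Lewis relation, all
  per-stage overridable;
* **core-vessel conductances**: `h_a = h_v = 0.01 C_bl` W/K, a
  calibration constant standing in for a detailed vessel-geometry
  derivation;
* **controller gains**: central/peripheral dilation 117 000 and
  7 500 cm³/(h·K), constriction 20 and 0.5 K⁻¹, shivering 19.4 W/K².
  These are classical multi-node magnitudes with the central
  constriction gain chosen so that the regulated neutral steady state
  (29 °C, 50 % RH, nude) lands at a head-core temperature of
  36.6–37.1 °C and an area-weighted mean skin temperature of 33–35 °C —
  both asserted by the test suite;
* **fixture humidities** (not stated with the protocols): 50 % RH in
  the neutral stages and 30 % RH in the 45 °C stages of the four-stage
  protocol; the warm-wall protocol holds the vapor pressure of its
  first stage (50 % RH at 23 °C) constant while the air temperature is
  lowered.

## Numerics

The default integrator is fixed-step fourth-order Runge–Kutta at 1 s —
the fastest vessel time constants are a few seconds, which the step
resolves stably, and a fixed-step scheme makes runs bit-for-bit
deterministic and conserves the enthalpy invariant exactly. Halving the
step changes the final state of the two-hour four-stage protocol by
less than 1e-3 K (asserted in the tests). An adaptive stiff solver
(`lsoda`) backs `equilibrate()`, which integrates toward the regulated
steady state and then polishes it with a damped Newton iteration in
heat-flux form (`C dT/dt`, W) to `max |dT/dt| < 1e-7` K/s; the raw-rate
form is numerically intractable because node capacitances span
18.7–67 160 J/K.

The printed sector-redistribution rule is scale-free in the sector
temperature deltas, so the perfectly symmetric state is a
non-differentiable, unstable fixed point: an infinitesimally warmer
sector immediately attracts a finite extra flow share. Two consequences
are handled deliberately. First, `equilibrate()` solves the steady
state in the reduced sector-symmetric subspace whenever the environment
is angularly uniform, so uniform scenarios start from an exactly
symmetric state. Second, the RK4 path performs identical arithmetic on
all four sectors, so uniform runs remain exactly symmetric for their
whole duration — the suite asserts a sector spread below 1e-9 K across
the full four-stage protocol. Under genuinely asymmetric boundary
conditions the redistribution behaves as intended, feeding hot sectors
preferentially.

Degenerate inputs: isothermal sectors split perfusion equally (avoiding
0/0); a negative per-sector share cannot arise on a four-sector ring
but is guarded by proportional clipping; evaporative capacity at or
below zero falls back to insensible wettedness; all state temperatures
are bounds-checked (0–60 °C) with the offending node named on failure.

## What the fixtures do and do not show

`fixture_scenario("uniform-fourstage")` reproduces the staging of a
classical chamber experiment (30 min each at 29/45/29/45 °C, shorts
only) and is used for trend and convergence checks: hot stages must
raise the mean skin temperature relative to the adjacent neutral
stages, and the head-core trajectory must stay within a physiological
envelope. `fixture_scenario("fanger-warmwall")` reproduces a classical
asymmetric-radiation protocol (a wall 0.5 m to the subject's left
stepped from 23 to 70.1 °C while air temperature is lowered to hold the
operative temperature); the wall-facing arm sector must run warmer than
the contralateral one at every heated stage, with a monotonically
widening gap.

These are *structural* validations. The packaged protocols contain no
digitised experimental traces, so passing them demonstrates correct
mechanics — conservation, symmetry, controller analytics, radiative
asymmetry of the right sign and ordering — not point-wise agreement
with any particular subject population. Individual anthropometry,
acclimatisation, exercise metabolism, counter-current limb heat
exchange and radiative shadowing between body parts are out of scope;
a single standard body is modelled.
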