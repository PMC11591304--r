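---
title: "Methods: pulsatile hemodynamics of an idealized type B aortic dissection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pulsatile hemodynamics of an idealized type B aortic dissection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tbadflow)
```

## The question the package addresses

In uncomplicated type B aortic dissection the aortic wall splits into a
*true lumen* (the original channel) and a blind *false lumen*, separated by
the intimal flap (septum). Blood enters the false lumen through a proximal
*entry tear*; a distal *re-entry tear* — whether spontaneous or created
surgically by fenestration — lets it return. Where along the septum such a
re-entry tear sits changes the pressure loading of the false lumen, the
wall shear stress (WSS) on the flap, and the extent of recirculating flow
in the blind pouch; these are the quantities a surgeon planning a
fenestration would like to anticipate.

`tbadflow` studies this question on a deliberately idealized,
two-dimensional model: eleven scenarios share one geometry and differ only
in the re-entry tear — absent (case 1) or centered 22.5, 33.7, 67.4, 89.9,
112.4, 134.9, 157.4, 168.6, 179.8 or 202.3 mm proximal to the false-lumen
floor (cases 2–11). Tears are sized at 50% of the false-lumen short axis
(6.4 mm for the default 12.8 mm pouch). The product of the sweep is the
*comparison across cases* — trends in regional pressure, WSS, tear flux and
recirculation — not absolute patient-specific values, which a 2D desk-scale
model cannot and does not claim to reproduce.

## Geometry idealization

The vessel is a straight channel of constant width equal to the true-lumen
width (20 mm by default). Within the dissected segment (225 mm) the false
lumen is modeled as an *outward pocket* attached to one side of the
channel: a parallel cavity of width 12.8 mm behind a 2 mm septum, sealed at
both ends by 2 mm caps and reached only through the septal tear gaps. The
proximal 60 mm of channel carries three branch outflow slots (6 mm wide, 5%
of inlet flow each) standing in for the arch branches; 20 mm of plain
channel follows the dissection distally. The dissected segment is
partitioned into six equal-length axial regions for reporting — anatomical
landmarks do not survive the idealization, and equal division is the only
reproducible choice.

Two design points deserve explanation:

* **Why an outward pocket rather than a channel split?** Splitting a wide
  proximal channel into a narrower true lumen creates an abrupt
  stair-step contraction immediately upstream of the entry tear. In early
  builds the vena-contracta suction of that contraction (hundreds of Pa at
  systole) overwhelmed the few-Pa axial friction drop between the tears and
  *inverted* the tear circulation. The outward pocket keeps the flowing
  channel prismatic, so the axial pressure distribution along the septum is
  monotone and tear circulation is governed by the physics of interest
  (friction and pulsatile inertia), not by a corner artifact of the
  rasterized contraction. Anatomically this corresponds to the common
  situation of a false lumen bulging outward from the original vessel
  line.
* **Stair-step rasterization.** Cells are square; a cell is fluid when its
  center lies in the fluid region (deterministic, no randomness anywhere).
  A rasterization refuses to proceed when a tear or lumen would span fewer
  than 3 cells, naming the offending feature.

## Boundary conditions and the velocity scale

The inlet applies a spatially flat, pulsatile velocity: a half-sine
systolic pulse over phases 0.05–0.45 s of a 1 s cardiac period, peaking at
0.25 s, on a zero diastolic baseline. The outlet applies a pulsatile
pressure between 10.6 and 16.0 kPa (about 80/120 mmHg) peaking at 0.30 s.
Branch slots prescribe outflow velocities computed *from the rasterized
widths* so that each slot carries exactly its configured fraction (5%) of
the instantaneous discrete inlet flow — the discrete analog of a flow-split
outlet. All waveform parameters are configuration-exposed; the shipped
shapes are documented parametric approximations of physiological traces,
interpolated by a periodic monotone (Fritsch–Butland) cubic so that
pressure positivity and peak values are exact.

The default peak inlet velocity is 0.125 m/s, not an aortic ~1 m/s, and
this is a deliberate **velocity-scale reduction**: blood viscosity and
density are physical (3.71 mPa s, 1060 kg/m³), but a 2D channel of
aortic width has hydraulic diameter `2w = 40 mm`, so a 1 m/s flat inlet
would put the model at `Re_max ≈ 24,000` — far beyond the critical
Reynolds number (~2300) of the laminar regime the model assumes, and
indeed such runs develop resolved Tollmien–Schlichting-type waves and lose
cycle periodicity. Matching both the physiological velocity scale and the
laminar regime is impossible in this reduction; the model keeps the
regime: `U_peak = Re_c · mu / (rho · D_h · 1.6) ≈ 0.125 m/s`, the 1.6
allowing for in-domain amplification. `max_reynolds()` reports the
realized value (about 1600–2500 across cases) and logs a warning, never an
error, if a configuration exceeds `Re_c`.

## Discretization and pressure–velocity coupling

The unsteady incompressible Navier–Stokes equations (continuity
`∇·v = 0`; momentum `ρ ∂v/∂t + ρ v·∇v = −∇p + ∇·τ` with the Newtonian
stress `τ = μ(∇v + ∇vᵀ)`) are solved on a staggered (MAC) Cartesian grid
with stair-step masking: pressures at cell centers, velocity components on
faces. Solid faces carry exactly zero velocity — no-slip on a rigid wall is
enforced identically, not approximately.

* **Convection** uses second-order one-sided upwinding, falling back to
  first order wherever the second upstream value would have to be
  extrapolated across a wall, and to a one-sided wall-distance gradient in
  the cell adjacent to the wall (the "gradient limiting at mask
  boundaries").
* **Viscous terms** are central second-order, explicit in time. Tangential
  wall closure uses the mirrored ghost value `u_ghost = −u₁` — the
  standard MAC treatment. A closed-form analysis of plane Poiseuille flow
  under this closure gives a *uniform* discrete error `a·h²/4` (with
  `u = a·y(w−y)`), i.e. a relative error of exactly `(h/w)²`; the measured
  benchmark errors (4% → 1% → 0.25% for h = 1, 0.5, 0.25 mm in a 5 mm
  channel) reproduce this, which is what makes the observed convergence
  order a sharp test.
* **Pressure–velocity coupling** is an incremental fractional-step scheme
  with the PISO structure: a momentum predictor including the lagged
  pressure gradient, then two pressure-correction sweeps per step. The
  pressure Poisson system (Neumann at walls and velocity-Dirichlet faces,
  Dirichlet at pressure boundaries) is assembled once per grid and solved
  with a cached sparse Cholesky factorization — fully deterministic, and
  accurate enough that the post-correction divergence is at machine level
  (measured ≲ 1e-13 s⁻¹ against a 1e-8 s⁻¹ acceptance tolerance) and
  global mass imbalance is ≲ 1e-15 of gross inflow.
* **Time stepping** is adaptive: `dt = 0.5·h/max|v|`, capped at 1 ms, with
  an explicit-diffusion cap `0.2·h²/ν`. Snapshots at requested phases are
  linear time interpolations of the bracketing steps.
* **Initial condition and cycles.** Runs start from rest at the diastolic
  outlet pressure and integrate four cardiac cycles; snapshots are taken in
  the fourth at phases 0.25 s (peak systole) and 0.47 s (early diastole),
  i.e. t = 3.25 s and 3.47 s. The cycle-3 vs cycle-4 velocity difference at
  matched phase is reported as the periodicity diagnostic.

Degenerate inputs fail loudly: a NaN in the state raises an instability
error suggesting a smaller step; a post-correction divergence above
1e-6 s⁻¹ raises a solver failure carrying the residual; a missing tear
requested from `tear_flux()` is an explicit error, and an empty
(region, lumen) cell set yields an `NA` row, never a silently dropped one.

## Validation benchmarks

Both analytic benchmarks drive a plain channel with pressure Dirichlet
conditions at *both* ends — a velocity inlet would prescribe the very
profile being validated.

* `poiseuille_benchmark()`: steady pressure-driven flow versus
  `u(y) = Δp/(2μL)·y(w−y)`; default 5 × 10 mm channel, 0.1 m/s centerline.
  Expected: < 2% maximum relative error at 0.5 mm spacing and observed
  order ≈ 2 across 1, 0.5, 0.25 mm.
* `womersley_benchmark()`: oscillatory pressure-driven flow versus the
  analytic oscillatory-channel profile (`womersley_profile()`), default
  6 mm channel at 1 Hz — Womersley number α ≈ 4, the physiologically
  interesting unsteady regime. The solver runs 8 forcing cycles from rest
  (the slowest transient decays at rate `ν(π/w)²` ≈ 0.96 s⁻¹, so the final
  cycle is clean); expected cycle-averaged L2 error < 5% at 0.5 mm, and the
  error itself is periodic (final two cycles agree).

## Post-processing definitions

* **WSS** at a wall-adjacent fluid cell is `μ` times a one-sided quadratic
  estimate of the tangential-velocity gradient, `(9u₁ − u₂)/(3h)`, through
  the wall zero and the two nearest cell-centered tangential velocities —
  second order and exact for parabolic profiles (the plane-Poiseuille value
  `6μU/w` is recovered to rounding). Samples whose second interior cell is
  missing are flagged unreliable and excluded from summaries.
* **Regional summaries** report, per region × lumen, the *median* cell
  pressure (kPa) and the median and max of reliable WSS samples (Pa), plus
  the peak speed. The median is used for both pressure and WSS for
  coherence; tear-gap cells belong to neither lumen and are excluded (they
  are reported as their own labels by `peak_velocity_location()`, with ties
  broken by lowest region, true before false lumen).
* **Tear flux** integrates the septum-normal velocity over the gap;
  positive means false → true lumen, so "blood returns to the true lumen"
  reads as a positive re-entry flux at systole.
* **Recirculation** is the fraction (and area) of false-lumen cells distal
  to the re-entry tear whose axial velocity is below
  `−0.01 × reference speed` (reference = peak inlet velocity). Vortex-core
  detection was rejected as under-determined on a coarse masked grid.
* **Mesh-sensitivity max WSS** (`wss_max_interior()`) is taken over
  reliable samples *within the dissected segment* and at least one septum
  thickness (2 mm) away from every re-entrant wall corner. This needs a
  word: at a re-entrant stair corner the continuum WSS is unbounded
  (`τ ~ r^{λ−1}`, λ ≈ 0.54), and at the flat-profile inlet plane a
  Blasius-type leading-edge layer gives `τ ~ x^{−1/2}`; a pointwise max
  over either cannot converge under refinement on *any* consistent scheme.
  The excluded structures are artifacts of the idealization (sharp
  rasterized corners, an abrupt inlet plane), not hemodynamics of the
  dissection, and the interior max is the grid-convergent analog of a
  smooth-geometry maximum.

## The case sweep and its study conditions

`run_sweep()` simulates the configured cases (all eleven by default) at
1 mm spacing, four cycles each, runs the full post-processing, and emits
tidy CSV tables, a JSON manifest keyed by a configuration hash, and a trend
report: (a) the true-lumen region-1 minus region-6 systolic pressure gap
per case, (b) per-region systolic false-lumen pressure and WSS relative to
the entry-only baseline, (c) recirculation versus re-entry distance,
(d) tear-flux directions per phase. The trend annotations are descriptive
output; the test suite asserts only the subset of qualitative claims that
proved robust on this model. Everything is deterministic — there is no
random number generation anywhere in the pipeline — so reruns are
bit-identical and per-case results are resumable from their hash-keyed
stores.

Problem sizes are chosen for a single-CPU desk run: the default sweep grid
(1 mm) puts ~10,000 fluid cells in play and a four-cycle case takes a few
thousand steps; the mesh study uses a shortened 100 mm dissected segment at
2.0/1.4/1.0/0.5 mm — the finest level an exact two-fold refinement of the
1.0 mm grid, so the finest pair shares the identical rasterized geometry
and measures pure discretization error — and all four levels complete in
minutes; the test suite
exercises a three-case subset {1, 2, 11} (entry-only, most distal tear,
most proximal tear) of the full sweep.

## What the model shows, and what it does not

The suite's sweep-level assertions document where the idealized model
agrees with expectations for dissection hemodynamics:

* Tear circulation direction: at peak systole blood enters the false lumen
  through the entry tear and returns through the re-entry tear
  (false → true); at early diastole, after inflow ceases, the trapped
  true-lumen momentum reverses the loop (true → false at the re-entry,
  returning via the entry tear). The sealed entry-only pouch carries zero
  net tear flow at machine precision, as mass conservation demands.
* The true-lumen inlet–outlet systolic pressure gap is largest for the
  most distal re-entry tear and relaxes toward the entry-only value as the
  tear moves proximally.

Three behaviors measured by the suite deliberately remain as *findings*
rather than passing assertions, because the idealized model genuinely
behaves differently from a smoothed, patient-specific 3D geometry:

* **Sub-tear recirculation extent is nearly invariant across tear
  locations** (~45–50 mm² reversed area at systole for every re-entry
  case). Distal tears drive a stronger false-lumen throughflow (larger
  inter-tear pressure drop) into a smaller sub-tear pocket; proximal tears
  drive weak flow into a vast one; the overshoot vortex at the tear lip
  comes out self-similar. Whether "recirculation is reduced for distal
  tears" then depends entirely on the reversal threshold: as the threshold
  tends to zero the geometric (zone-size) effect dominates and distal
  tears do show less recirculation; at the configured 1% threshold the two
  effects cancel. The threshold is a declared design parameter and is not
  adjusted to manufacture a trend.
* **Distal false-lumen systolic pressure in re-entry cases sits a few Pa
  *above* the sealed baseline, not below.** In the 2D slot geometry the
  entry jet enters perpendicular to the septum and recovers part of its
  dynamic head (~0.5·ρ·u²_tear) in the pouch, which at this velocity scale
  slightly exceeds the laminar true-lumen friction drop between the tears.
  Among re-entry cases the expected ordering does hold (the more distal
  the tear, the lower the false-lumen pressure).
* **The pointwise max-WSS does not reach the 5% mesh-sensitivity band at
  desk-scale resolutions.** Even restricted to the dissected segment and
  away from corners, the maximum sits in a transient Stokes boundary layer
  about 0.9 mm thick, and the stair-step feature boundaries snap by up to
  half a cell between levels; measured finest-pair changes are 14% at
  1.0/0.5 mm and 8% on a 2.0/1.0/0.5/0.25 mm halving chain (order ≈ 0.8).
  The mesh study reports the full table with changes against both
  neighbouring levels so the behavior is visible rather than hidden.
* **Four cycles do not fully periodicize the most distal tear case.** The
  false-lumen corridor from entry to a distal re-entry tear has a transit
  time of several seconds (~0.04 m/s over ~200 mm), so its spin-up is
  incomplete within four cycles: cases 1 and 11 reach cycle-3/4 agreement
  well under 1%, case 2 about 4%. The four-cycle protocol is part of the
  study conditions and is kept.

## What the synthetic generator does and does not emulate

The geometry factory emulates the *topology* of a dissected descending
aorta — two lumens, a sealed pouch, septal tears at controlled positions,
arch branch takeoffs — and the sweep design around it. It does not emulate
curvature of the arch, the spiral course of a real false lumen, septum
motion (rigid walls), non-Newtonian rheology, turbulence, or 3D secondary
flows. Passing tests therefore demonstrate internal correctness of the
solver and the comparative machinery on the idealized model; they do not
certify patient-specific magnitudes, and the package intentionally reports
trends, not clinical values.

## Known limitations

Rigid no-slip walls; laminar Newtonian flow at a reduced velocity scale;
2D planar reduction; prescribed (not pressure-coupled) branch flow splits;
stair-step walls whose corners require the exclusion rules described
above; four-cycle periodicity limits for long false-lumen corridors. All
tunable parameters discussed here live in a single YAML configuration
(`inst/extdata/default_config.yaml`) with the defaults annotated.
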