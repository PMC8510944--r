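---
title: "Models and numerics behind blasttube"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics behind blasttube}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

blasttube models a confined-space blast-tube experiment end to end: the gas
dynamics that set the exposure, the finite-volume simulation of the blast
wave in the tube and the closed test room, the waveform metrics that
quantify the exposure, and the small-cohort statistics used to relate
exposure to injury and outcome. This vignette records the models, the
numerical choices, and what the package's tests do and do not establish.

## Shock-tube theory

The driver (state 4) and driven (state 1) sections are ideal air
(γ = 1.4, R = 287 J kg⁻¹ K⁻¹) at a common temperature, taken as 293 K. The
tube's operating temperature is not part of the published configuration;
293 K is a package default, stated here once, and every relation accepts
arbitrary `gas_state()` inputs. With equal temperatures the driver/driven
sound speeds are equal and the diaphragm closure depends only on the
pressure ratio:

$$\frac{P_4}{P_1} = \frac{2\gamma M_s^2 - (\gamma-1)}{\gamma+1}
 \left[1 - \frac{\gamma-1}{\gamma+1}\Big(M_s - \frac{1}{M_s}\Big)\right]
 ^{-2\gamma/(\gamma-1)}.$$

`mach_from_p4p1()` inverts this by bisection on the feasible interval
(bracketed away from the expansion-limit Mach number where the bracketed
term vanishes) followed by a Newton polish to a 10⁻¹² relative tolerance;
the forward relation is strictly increasing, so the root is unique. At the
22.5 operating ratio the closure gives Ms = 1.866, about 0.4 % above the
measured 1.859; conversely, the measured Ms maps back to a ratio of 22.0.
The ~2 % gap is treated as the rounding of a published operating point, and
the tests use the corresponding bands (1 % on Ms, 3 % on the ratio).

A real double diaphragm ruptures slowly and incompletely, so the nominal
bottle pressure overstates the shock actually produced.
`effective_driver_pressure()` encodes the calibrated operating point
(3.0 MPa nominal → 2.3 MPa effective) and scales the other nominal settings
by the same 2.3/3.0 factor — a documented package convention, since only
the 3.0 MPa point was ever calibrated against measurement.

## The WAF solver

The compressible Euler equations are solved with the weighted-average-flux
(WAF) scheme: a second-order TVD finite-volume method whose intercell flux
is a Courant-number-weighted average across the local Riemann fan. The fan
states are HLLC (with a passively advected transverse velocity); the
star-pressure estimate is adaptive (linearised PVRS for mild jumps, the
two-rarefaction or two-shock approximation otherwise), which keeps the wave
speed bounds tight at the strong (~22×) diaphragm jump. TVD limiting uses
the van Leer limiter mapped onto the WAF weights, with the density jump
across each wave as the limiting quantity. The exact Riemann solver is kept
as an independent oracle: the Sod benchmark at 400 cells lands at an L1
density error of ~0.0015, and a single shock initialised from the jump
relations tracks Ms·a₁ to well under 1 %.

Two dimensions are handled by dimensionally split sweeps with alternating
order. The axisymmetric radial sweep uses r-weighted flux volumes — the
update divides the difference of face-radius-weighted fluxes by the cell
center radius — with only the p/r pressure source on radial momentum. The
alternative (plain Cartesian sweeps plus an explicit −H/r source) is
simpler to describe but cannot conserve mass exactly; the geometric form
telescopes, so closed-domain mass and energy are conserved to rounding
(the suite asserts 10⁻¹⁰ over 1000 steps, observed drift is zero to double
precision). Uniform states are exact steady states of the radial update,
and r-invariant planar data reduces row-by-row to the 1D scheme (asserted
to 10⁻¹²).

Walls are stair-stepped solid cell masks. Sweeps operate on contiguous
fluid segments with two mirrored ghost cells at each wall (normal velocity
negated); the two wall-adjacent interfaces of each segment use pure HLLC
upwinding (WAF weight φ = 1) so that the wall mass and energy fluxes vanish
identically for mirrored states — the price is first-order accuracy in the
one cell adjacent to a wall, which the reflected-shock benchmark (analytic
reflected-pressure ratio, 2 % band) absorbs comfortably.

Time steps are global CFL (default Courant number 0.4, both sweep
directions), with the first five steps taken at a fifth of the CFL step —
the initial diaphragm discontinuity launches waves faster than the
pre-rupture signal-speed estimate. A `dt` below 10⁻¹² s raises a stagnation
error; any non-positive density or pressure aborts with the offending cell
index and time.

Adaptive mesh refinement is deliberately out of scope: the published
simulation names an adaptive method with a 5 mm initial mesh but records
none of its criteria, so the package's supported mode is a uniform grid at
configurable resolution. The confined-room observables reported by the
package are mesh-converged: 20, 10 and 5 mm grids agree within 1 %.

## The blast-tube scenario

The axisymmetric domain is chamber (r 160 mm × 0.5 m), channel
(r 160 mm × 5.8 m) and closed test room (r 1.4 m × 2.78 m), 9.08 m of axis
in total. The nozzle flares from the channel radius to the 200 mm
outlet-window radius and protrudes 1.2 m into the room as a thin conical
wall: the published tube length (~7.5 m) minus chamber and channel fixes
the 1.2 m, and the room then extends 1.58 m beyond the outlet window, which
is consistent with the specimen position 0.65 m from the window. The wall
is one cell thick when the mesh is coarser than the physical 5 mm plate
(a warning notes the stair-step fallback).

`t0` is anchored to the incident shock reaching the nozzle mid-section on
the axis — not to diaphragm rupture, which the model deliberately does not
represent. Wall "arrival" is the first 5 kPa overpressure crossing
(≈5 % of ambient): large against numerical ripple, small against the
±30.4 kPa classification used for pressure maps. Probe stations are only
published graphically, so `default_probes()` documents a layout (chamber,
diaphragm station, four channel stations, nozzle entrance, and two room
probes 200 mm apart) and everything is configurable.

Simulated observables at 2.3 MPa effective driver, 10 mm mesh: the shock
exits the nozzle ≈1.0 ms after t0, the far axial wall first crosses 5 kPa
at t0 + 4.46 ms, and the cylindrical (lateral) wall at t0 + 4.25 ms. The
far-wall timing sits 6 % from the published 4.75 ms. The published lateral
timing (3.35 ms) is earlier than ours by 27 %: it implies a diffracted
radial wave averaging ~510 m/s over the 1.2 m to the wall, faster than the
jet-supported axial front — in this inviscid model the diffracted front
decays to near-acoustic speed within half a metre of the lip, as classical
shock-diffraction theory predicts, and the ordering is reversed. The
discrepancy is resolution-independent here and is reported as computed
rather than adjusted.

Late-time behaviour: energy balance caps the room's equilibrated
overpressure at roughly +5 kPa (driver excess energy ≈ 220 kJ over a
~17 m³ room), and the simulation settles to a +4 to +10 kPa room mean with
sloshing waves and persistent inviscid vortex cores tens of kPa below
ambient — the pointwise "everywhere above ambient" reading of the
confined-space buildup is not physically attainable, while the room-mean
buildup (and its absence when the far wall is opened) is, and both are
tested as such.

Out of scope, as in the published analysis: the animal body, table and
fixtures, the armor plate as an obstacle, diaphragm rupture mechanics,
viscosity, heat transfer and 3D effects.

## Waveform metrics

Traces are uniform-rate overpressure records. Arrival is the first upward
threshold crossing (linearly interpolated); the positive phase ends at the
first zero down-crossing after the peak — not the global minimum, because
confined-room records carry reflected arrivals that a global rule would
swallow; impulse is the trapezoidal integral of the positive lobe.
Friedlander fits use Levenberg–Marquardt with starting values from the
metrics, time measured from the first retained sample (which removes the
sub-sample arrival-offset bias for sharp rises); the relative RMS residual
is reported so model mismatch (e.g. a square pulse) is flagged, never
hidden. The ±30 % ternary classification reproduces the ±30.4 kPa rule at
standard ambient.

## Cohort statistics

The packaged fixture transcribes the published 17-animal necropsy table
(6 armored, 11 not; remark keywords LH, Hemothorax, Splenic, Liver, IAH,
BR). The two-sided Fisher test uses the probability-mass rule — the sum of
hypergeometric probabilities of tables no more probable than observed, with
a 1 + 10⁻⁷ tie guard — which reproduces the published p = 0.009 for the
arrest × outcome table; the odds ratio is the conditional MLE under the
noncentral hypergeometric model (0/∞ at boundary tables, a degenerate
margin yields p = 1 with a flag). An independent factorial-enumeration
oracle and `stats::fisher.test` cross-check it in the tests. Reported
percentages round half away from zero (6/11 → 55 %).

The repeated-measures ANOVA is the univariate split-plot decomposition via
`stats::aov` with a subject error stratum: group against
subject-within-group, time and group × time against the residual. No
sphericity correction is applied by default (none is named in the modelled
analysis); Greenhouse–Geisser is available as an option. A brute-force
cell-means sums-of-squares oracle pins the F statistics to 10⁻⁹, and under
the null generator the group test's type-I error is calibrated to
[0.03, 0.07] at α = 0.05 over 2000 replicates — the group test is exact
under any within-subject covariance, which is why AR(1) noise does not
distort it. The t-test is pooled-variance Student (the equal-variance
assumption is stated, not inferable from the source), with explicit
conventions for zero-variance degeneracies.

## Synthetic generators

The cohort generator encodes the study's structural hypotheses as a
generative model, not as fitted estimates: every exposed animal has lung
hemorrhage; arrest is Bernoulli with
logit⁻¹(β₀ + β₁ α^armor · dose); arrested animals recover with probability
ρ; death occurs iff arrest goes unrecovered. The logistic link and the
multiplicative attenuation α are conventions of this package. Defaults
(β₀ = −1.818, β₁ = 0.02 kPa⁻¹, α = 0.562, ρ = 3/8, dose 100 kPa) are
chosen so the expected counts at the study's group sizes match the
published outcome margins exactly (8 arrests, 3 recoveries among 17) —
a calibration of the generator to printed totals, not a fit to animal-level
data. `recover_armor_effect()` maximises the exact likelihood in
(β₀, β₁, log α); α is flagged unidentifiable when the dose effect is
statistically indistinguishable from zero, since α enters only through
β₁ — a single-dose design cannot identify it, so recovery studies vary the
dose (40–160 kPa here).

Physiological series are stratum-mean trajectories plus AR(1) deviations
(φ = 0.5 by default); animals that die contribute only the pre-injury and
5-minute records, mirroring deaths within the first hour. The default
trajectories are illustrative swine values — the study's animal-level
physiology exists only as figures — so tests against them calibrate the
statistical machinery (type-I error, power at a configured effect size),
and deliberately say nothing quantitative about real animals. All
generators take explicit seeds, are bit-reproducible, and restore the
global RNG state.

## Problem sizes and determinism

The shipped tests run the room scenario once at 10 mm mesh to t0 + 20 ms
(~1 minute), the Sod benchmarks at 100–400 cells, the conservation box for
1000 steps, and the stochastic calibrations at 2000 (ANOVA), 12 × 2000
animals (α recovery) and 200 (Friedlander) replicates — sizes chosen to
give each check clear resolution while keeping a full run in minutes. The
solver is deterministic; every stochastic component is seeded.

## Known limitations

Inviscid, single-species ideal gas; no fluid–structure interaction, so
simulated traces lack the fixture reflections present in measured ones;
stair-stepped geometry (exact here except the nozzle lip at coarse
meshes); no AMR; the lateral-wall timing discrepancy discussed above; and
the synthetic physiology is calibration scaffolding, not a biological
model.
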