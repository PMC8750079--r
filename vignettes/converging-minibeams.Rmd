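---
title: "Modelling magnetically converged proton minibeams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling magnetically converged proton minibeams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Proton minibeam radiation therapy (pMBRT) delivers dose through an array of
planar, sub-millimetre beams. Healthy tissue at shallow depth sees a strongly
modulated dose — high peaks on the minibeam axes, low valleys between them —
while multiple Coulomb scattering (MCS) homogenizes the dose near the Bragg
peak, where the target sits. The spatial modulation is summarised by the
peak-to-valley dose ratio (PVDR) and by the valley dose; higher PVDR and
lower valleys at shallow depth correlate with better normal-tissue sparing.

A way to improve both is to enlarge the centre-to-centre (ctc) distance
between minibeams and then *converge* them magnetically so that the
transverse dose pattern at the Bragg peak is unchanged relative to a
reference delivery with a smaller ctc. `minibeamr` models this design loop:

1. geometry of a divergent multislit collimator and a pencil-beam-scanning
   (PBS) spot grid (`pmbrt_collimator()`, `spot_grid()`, `make_scenario()`);
2. per-slit, per-energy optimization of a dipole field placed after the
   collimator, or of a uniform field inside the water phantom (an MRI-like
   scenario), so that each minibeam lands on the reference position at its
   Bragg peak (`solve_dipole_field()`, `solve_phantom_field()`,
   `build_field_table()`);
3. a beamlet-superposition dose engine in the phantom (`compute_dose()`);
4. spatial-fractionation metrics (`pvdr_series()`, `valley_series()`,
   `flat_region_discrepancy()`, `bragg_retraction()`);
5. genetic-algorithm optimization of spread-out Bragg peak (SOBP)
   energy-layer weights (`sobp_dose_library()`, `ga_optimize()`).

Five named scenarios are built in: `config1` (reference, ctc 4 mm, no
field), `config2`/`config2p` (ctc 6 mm, 50 mm dipole after the collimator,
with a static multislit or a dynamic scanning aperture) and
`config3`/`config3p` (ctc 6 mm, uniform in-phantom field).

## Beam transport model

**Kinematics and ranges.** Protons are characterised by kinetic energy E
(MeV); momentum is the exact relativistic `sqrt(E(E + 2m))` with
m = 938.272 MeV, and the magnetic rigidity is p/q, so the Larmor radius in a
field B is `magnetic_rigidity(E)/B`. Ranges in water come either from the
Bragg–Kleeman power law `R = alpha E^p` (alpha = 0.0022 cm·MeV^-p,
p = 1.77, the default) or from a bundled CSDA table interpolated with a
monotone log–log spline; the two agree within 2% over 70–230 MeV and both
invert to 0.1%. Energies above 230 MeV are outside the model.

**Trajectories in a field.** A minibeam central axis entering the phantom at
angle alpha obeys

    dx/ds = sin(alpha),  dz/ds = cos(alpha),  dalpha/ds = -B / Brho(s),

with the rigidity evaluated at the residual range R(E) − s along the arc
length s: the proton bends ever harder as it slows down. The integrator is a
classical fixed-step RK4 in arc length (default step 0.1 mm) with a fixed
fine tail (0.01 mm steps over the last 2 mm), because the curvature grows
like (residual range)^-0.28 towards the end of range and a uniform step
would lose accuracy exactly where the landing position is decided. Halving
the nominal step moves the landing position by well under 0.1 µm. For a
dipole in air the same integrator runs at constant energy; for thin dipoles
the closed-form Larmor kick `phi = theta - asin(dz_dip / r)` agrees with the
tracked kick to ~0.04% whenever r >= 20 dipole thicknesses.

**Field optimization.** The reference landing position of a slit at x1 is
the straight drift `x2 = x1 + (dz_coll + dz_air + R(E)) tan(theta(x1))`
through the 65 mm collimator, the 70 mm air gap and the in-water range, with
the slit tilt theta = 0.025 deg/mm × x1. For each enlarged-ctc slit, a Brent
root search finds the field (bracket 0–10 T, landing tolerance 1 µm) that
lands the minibeam on the reference position of the index-matched 4 mm-ctc
slit. A trajectory that curls out of the phantom at a large trial field is
scored at its lateral exit position, which keeps the bracket monotone.

**Dipole drift conventions.** For the dipole scenarios the post-kick drift
is configurable. The default (`"air+range"`) tracks the beam through the
collimator and dipole along the slit tilt and then drifts through the
remaining air plus R(E) along the exit angle, so at B = 0 the landing
reduces exactly to the reference equation. A `"range-only"` convention
(drift of R(E) from the dipole exit with the in-dipole displacement
neglected) and a `"dipole-center"` convention are also available, because
the geometry leaves the effective drift origin ambiguous. None of the
conventions reproduces the published dipole field table quantitatively
(the in-phantom table is reproduced, and the dipole table qualitatively —
linear growth with off-axis distance, decrease with energy); the dipole
setup evidently involves effective distances not fully stated.

## Dose engine

The engine is a deliberate desk-scale stand-in for Monte Carlo transport.
Every (PBS spot, slit) pair with a nonzero transmission emits a *beamlet*:

* static multislit: the transmission is the integral of the spot's lateral
  Gaussian (sigma 3 mm at the collimator by default — a "few millimetres"
  class machine; the true value is machine-specific and exposed) over each
  slit aperture, so spots also feed neighbouring slits;
* dynamic aperture: each spot feeds exactly the aligned slit, weight 1.

The beamlet axis is tilted with its slit, kicked by the dipole field
assigned to the *spot's* x coordinate, or curved in-phantom by RK4. In the
static + field configurations part of each minibeam's flux is therefore
deflected with a non-optimized field — the minibeam broadening mechanism
that the dynamic aperture eliminates (the test suite checks the resulting
FWHM ordering at mid-range). Spots beyond the outermost slit receive a
proportionally extrapolated field, consistent with the near-linear
field-versus-offset correlation.

Dose deposition along the axis is parameterised by *path length*, so a
curved trajectory retracts its Bragg peak in depth exactly as the geometry
dictates. The depth dose is a Bortfeld-style analytical Bragg curve: the
Bragg–Kleeman stopping-power term `(R - z)^(1/p - 1)` plus a linear
fluence-loss term with beta = 0.012 cm^-1, gamma = 0.6 and a low-energy
spectrum-tail fraction epsilon = 0.2, cell-averaged across the integrable
peak singularity and convolved with a Gaussian combining range straggling
(`0.012 R^0.935` mm) and the range spread of a 1% dE/E machine energy
spread (a typical clinical PBS figure; `bragg_depth_dose()` alone defaults
to straggling only, which puts the curve maximum about one straggling sigma
proximal of R). The lateral profile is the slit rectangle convolved with a
Gaussian whose width accumulates Fermi–Eyges moments of the Highland
scattering power (X0 = 360.8 mm) over the water path, added in quadrature to
a 0.2 mm source sigma; profiles are deposited as exact voxel averages, with
the right-tail antiderivative rearranged so that valleys many sigma from a
peak are computed without catastrophic cancellation. The y profile is the
45 mm slit length convolved with the same sigma. Doses are relative
(arbitrary units per simulated fluence); absolute calibration is out of
scope, which is why cross-configuration profile comparisons normalize by
the flat-region mean.

Two grids are provided: the full phantom grid (0.1 × 2 × 1 mm voxels,
1000 × 50 × 300) and a coarse grid (0.2 × 10 × 2 mm, 500 × 10 × 150), the
default for tests and the acceptance script. A single-energy coarse dose
computation takes a few seconds; the full end-to-end acceptance run
(21 field solves, two coarse grids, a GA run) takes well under a minute.

## Metrics

`pvdr_series()` follows the study's definition: the peak is the dose *on the
central minibeam axis* (x = 0, averaged over a central 10 mm y window), the
valley is the minimum dose strictly between the central and the first
off-axis minibeam peak, located per depth slice because converging
minibeams shift with depth. A zero valley is reported as an infinite PVDR
with a flag rather than an error. `flat_region_discrepancy()` compares two
transverse profiles over the region where a peak-top-interpolated envelope
of the reference reaches 95% of its maximum; the envelope interpolation
exists because minibeam profiles are oscillatory and a raw threshold would
select only peak cores, and outside the outermost peaks the envelope
follows the profile roll-off itself. The Bragg-peak depth at which profiles
are compared is the maximum of the *laterally integrated* depth dose — on a
minibeam grid the central-axis dose is entrance-dominated (lateral spread
dilutes the peak), and the integrated curve is also second-order
insensitive to the small path-length differences of converged beams.

`bragg_retraction()` reports R(E) minus the depth reached when the
integrated path length equals R(E); it vanishes at B = 0 and grows
approximately quadratically with the field.

## SOBP optimization

The per-layer library holds central-minibeam peak-dose depth curves on a
common grid — analytic Bragg curves by default, or curves extracted from
engine dose maps (`source = "engine"`). The five standard layers are 150,
154, 158, 162, 166 MeV; their Bragg peaks are stated to lie between 157 and
187 mm, with the flattening window equal to that span. Our broadened
Bortfeld + CSDA model realizes the peak maxima ~2–3 mm shallower, so
`sobp_dose_library(peak_align = c(157, 187))` applies a linear depth
calibration mapping the realized first/last peak maxima onto the stated
span, the way measured peak depths calibrate a commissioned range model.
Without it the window's distal edge hangs past the deepest peak and no
weight vector can flatten it.

The fitness is the maximum dose error `max(Dp) - min(Dp)` of the combined
curve `Dp(z) = sum_i w_i Dp_i(z)` over the window, reported relatively as a
percentage of the window mean. Because the absolute fitness is
scale-degenerate (all weights to zero is "perfectly flat"), the
highest-energy layer weight is fixed at 1 — weights are conventionally
reported normalized to the distal layer anyway — and the remaining layers
evolve on a log scale. The GA uses tournament selection (size 3), two
elites, arithmetic crossover (rate 0.9) and Gaussian mutation (per-gene
rate 0.2, sigma 0.1 on log weights), population 60 over 300 generations,
with a mandatory seed; fixed seed implies identical output, and the
best-so-far fitness is non-increasing by elitism. On a library constructed
so that known weights give an exactly flat plateau (`make_fixtures(
"toy-library-5")`, raised-cosine partition-of-unity lobes) the GA recovers
the planted weights to well under 2%, and on a two-layer toy library it
matches an exhaustive grid search.

One caveat worth stating plainly: with the analytic five-layer library the
optimizer's landscape is nearly flat along the first-versus-second layer
direction (the strictly-increasing solution costs under 0.01 percentage
points of fitness relative to the unconstrained optimum), and the true
optimum has the first layer marginally *above* the second, unlike the
published full-Monte-Carlo weight tables, which increase strictly with
energy. Layers two to five do increase strictly. The inversion is an end
effect of the window's proximal edge, which the first layer must hold up
alone; curve families with different proximal pedestals tip the same
degeneracy the other way.

## What the synthetic scenarios do and do not emulate

The generator reproduces the study conditions: collimator (15 slits,
0.4 × 45 mm², 65 mm thick, tilt 0.025 deg/mm, ctc 4/6 mm), 70 mm air gap,
50 mm dipole, 10 × 10 × 30 cm³ phantom, 31 × 17 spot grid (dy 3 mm, dx =
ctc) and the monoenergetic energies 100/150/200 MeV. It does **not** model
nuclear secondaries, collimator scatter or edge effects, fringe fields, or
MC noise. Consequences to keep in mind:

* entrance valleys are pure Gaussian tails — many sigma from any peak — so
  entrance PVDRs are astronomically large in *every* configuration and only
  their ordering and ratios are meaningful; published absolute PVDR tables
  (which include scatter floors) are not desk-reproducible, and the tests
  assert ordering properties instead;
* the dipole-configuration field table is reproduced only qualitatively
  (see the drift-convention discussion);
* passing tests show that the *mechanisms* — convergence, broadening,
  homogenization at depth, retraction — behave as in the study, not that
  absolute doses would match a Monte Carlo system.

## Numerical choices

* Lengths in mm, energies in MeV, fields in tesla, angles in radians;
  degrees only at config boundaries (tilts are quoted in deg/mm).
* Field solver: Brent on [0, 10] T, landing tolerance 1 µm; the landing is
  strictly monotone in B so ties cannot occur.
* RK4 step 0.1 mm plus the 0.01 mm end-of-range tail; curvature lookup
  precomputed per (energy, range model) and shared across solver iterations.
* Bragg curves are tabulated at 0.1 mm and linearly interpolated; profiles
  are exact voxel averages (see the cancellation note above).
* Degenerate inputs: empty energy lists give empty field tables; a
  single-slit, zero-tilt scenario gives a single ridge; uniform grids give
  PVDR 1; infeasible solver targets report the achievable landing window.
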