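---
title: "Quantifying Fontan hemodynamics from 4D-flow velocity fields"
author: "fontanflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Fontan hemodynamics from 4D-flow velocity fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fontanflow)
```

## The problem

In Fontan palliation the systemic venous return (SVC and IVC) is routed
directly into the pulmonary arteries — a total cavopulmonary connection
(TCPC) — with no subpulmonary ventricle to push blood through the lungs.
The circulation therefore lives or dies on the passive efficiency of the
cavopulmonary pathway. 4D-flow CMR measures all three velocity components
over the cardiac cycle in a volume, and from that single acquisition one
can quantify branch flows, how each caval stream distributes to the
pulmonary arteries, how much kinetic energy the flow carries and how fast
viscosity dissipates it, and how skewed the conduit jet is.

`fontanflow` implements that quantification chain on segmented velocity
fields: gridded three-component velocities in cm/s (the phase-contrast VENC
convention) on a regular voxel grid with physical mm spacing, plus an
integer lumen mask naming the vessel segments. All geometry lives in a
right-handed mm frame with voxel centers at `origin + (index - 1) *
spacing`; velocities are converted to SI only inside the energetics.

## Plane-based flow quantification

An `AnalysisPlane` is an oriented disc (origin, unit normal, radius)
placed across a vessel, normal pointing in the physiologic flow direction.
`planeFlux()` rasterizes the disc at 0.5 mm pitch (sub-voxel quadrature),
samples the field by trilinear interpolation, restricts to lumen samples
(nearest-neighbor mask lookup) and integrates the through-plane component:
\[ Q = \sum_i (v_i \cdot \hat n)\, \Delta A . \]
Net flow is the phase-duration-weighted cycle mean, reported in l/min and
optionally indexed to body surface area. The mean section velocity is the
area-averaged \(|v \cdot \hat n|\).

Derived circulation parameters follow directly:

* **QSPC** (systemic-to-pulmonary collateral flow)
  \(= (Q_{LPV} + Q_{RPV}) - (Q_{RPA} + Q_{LPA})\): the pulmonary venous
  return in excess of the cavopulmonary inflow must have arrived through
  collaterals. Because QSPC is a small difference of large flows, it
  inherits the *common* bias of the flux measurement only to the extent
  that veins and arteries are measured the same way — which is exactly the
  situation in a single CMR exam, and the situation our validation
  reproduces by measuring all four vessels with the same tube instrument.
* **Effective cardiac index** \(= (Q_{Ao} - Q_{SPC}) / BSA\).
* **Branch asymmetry**: RPA-dominant when \(Q_{RPA}/Q_{LPA} > 1.56\)
  (strict), LPA-dominant below 0.75, symmetric otherwise.

## Streamline caval distribution

`traceStreamlines()` seeds points uniformly at random over the
lumen-intersected seed disc (deterministic per seed) and integrates them
forward through the interpolated field with an adaptive Dormand–Prince
Runge–Kutta 4(5) stepper (relative tolerance 1e-4, absolute 1e-6 mm, step
advance capped at 5 mm). A line ends when it leaves the lumen (the crossing
is bisected onto the boundary), exceeds 500 mm of arc, or stalls below
0.1 cm/s. `classifyOutlets()` labels each exited line by the outlet segment
containing its terminal point (2-voxel dilation tolerance) and reports the
percent distribution over resolved lines; stalled, overlong and unmatched
lines are excluded from the denominator and reported separately, so the
RPA/LPA percentages always sum to 100.

Choices worth making explicit:

* **Time-averaged field by default.** Fontan caval flow is quasi-steady;
  tracing through the cycle-averaged field is the robust default, and a
  `single_phase` mode exists for phase-resolved work. The same default
  applies to the section shape metrics.
* **Uniform seeding.** Seeds are uniform over the disc, matching the
  line-count semantics of visualization tools; the physically
  flux-weighted alternative would weight by through-plane speed. On the
  junction phantom the two coincide by construction (plug inlet profile).
* **Velocity sampling at the domain edge.** The tracer samples the field
  with nearest-edge (clamp) extrapolation beyond the voxel-center hull.
  With zero-padding instead, an open outlet at the grid boundary reads as
  an artificial half-voxel layer of zero velocity and lines "stall" just
  before exiting; clamping keeps open ends open.

The integrator itself is validated against closed-form circular orbits
(rigid rotation \(v = \omega \times r\)): traced points must hold their
radius to 0.5% over a revolution — trilinear interpolation is exact for
linear fields, so this isolates the stepper error.

## Energetics

With blood density \(\rho\) and dynamic viscosity \(\mu\)
(`fluidConstants()`, defaults 1060 kg/m^3 and 3.5 mPa s — standard blood
values, configurable):

* **Kinetic energy**: voxel density \(\tfrac12 \rho |v|^2\), integrated
  over a volume of interest and divided by its volume. 1 J/m^3 equals
  1 uJ/ml, so volume-normalized results print directly in uJ/ml.
* **Viscous energy loss**: the strain-rate tensor
  \(e_{ij} = \tfrac12(\partial_j v_i + \partial_i v_j)\) is estimated by
  mask-aware finite differences — central where both axis neighbors are
  lumen, one-sided at the lumen boundary; voxels with no lumen neighbor
  along some axis are excluded and counted. The dissipation density is the
  incompressible Newtonian form \(\phi = 2\mu\, e_{ij} e_{ij}\), reported
  volume-normalized in uW/ml. Divergence-penalty terms are omitted:
  measured fields are not exactly solenoidal and the plain double
  contraction is the standard choice; this is a known small bias.
* **EL/KE index** \(= EL_{norm}/KE_{norm}\) (1/s): energy dissipated per
  second relative to the energy present — a flow-efficiency marker that,
  unlike EL itself, does not grow with flow. For Poiseuille flow in a tube
  of radius R the index is \(12\mu/(\rho R^2)\), independent of velocity:
  narrower pathways are intrinsically less efficient, which is the
  mechanism behind the inverse association of the index with pulmonary
  artery diameter.

Both quantities are computed per phase and reported as the cycle average
(equal phase durations); single-phase phantoms reduce trivially. Whether a
study should use cycle-averaged or peak-phase values is not settled; the
per-phase profile is kept in the result object so either can be read off.

The volume of interest for Fontan energetics is assembled from named mask
segments (`voiFromSegments()`), optionally clipped by half-space planes —
the conventional choice is the confluence clipped ~15 mm out on each limb,
matching cutting planes placed about 1.5 cm from the bifurcation.

## Section shape metrics

On one plane (`sectionShape()`):

* **Jet angle**: angle between the flux-weighted mean velocity vector and
  the plane normal, in degrees. The plane normal, not a vessel centerline,
  is the reference axis; planes are expected to be placed perpendicular to
  the vessel, where the two coincide.
* **Eccentricity**: in-plane displacement of the \(|v \cdot \hat
  n|\)-weighted flow centroid from the geometric lumen centroid, divided by
  the equivalent lumen diameter \(2\sqrt{A/\pi}\). This normalization
  yields the small magnitudes (a few hundredths) typical of conduit flow.
* **Mean WSS**: \(\mu \langle |\partial v_t/\partial n| \rangle\) over the
  lumen boundary contour. The wall is placed midway between the last lumen
  and first background raster cell; the wall-normal gradient is a linear
  one-sided difference over one voxel spacing with zero velocity imposed at
  the wall. The inward normal is taken radially toward the section
  centroid: vessel sections are near-convex, and radial normals are robust
  to the rasterized contour's staircase (an axis-aligned normal
  underestimates the gradient by roughly \(\cos 45^\circ\) on diagonal
  contour segments). On the 1 mm Poiseuille oracle this estimator sits
  about 13% low — near-wall trilinear smoothing against zero-valued
  exterior voxels — which is inside the 15% band we consider achievable at
  clinical resolution, and is the reason WSS is reported as a sectional
  mean rather than a local map.

## The phantoms: what they emulate, what they do not

Since patient acquisitions are private, validation runs on analytic
phantoms that attach machine-readable ground truth for every estimated
quantity; generators and estimators share no code paths.

* `poiseuillePhantom()`: steady laminar pipe flow,
  \(v(r) = v_{max}(1 - r^2/R^2)\). Closed forms:
  \(Q = v_{max}\pi R^2/2\), \(KE_{norm} = \rho v_{max}^2/6\),
  \(EL_{norm} = 2\mu v_{max}^2/R^2\), \(EL/KE = 12\mu/(\rho R^2)\),
  \(WSS = 2\mu v_{max}/R\). Optional sinusoidal pulsatility
  \(1 + a\sin(2\pi t/T)\) scales the energetic truths by the mean squared
  modulation \(1 + a^2/2\).
* `tiltedJetPhantom()`: the same tube carrying a jet tilted by a known
  angle and/or displaced off-center. The offset fraction is defined as
  displacement over the equivalent lumen diameter (2R) — the same
  normalization the eccentricity estimator uses, so the phantom's ground
  truth is the number the metric should recover; the jet radius shrinks by
  the displacement so the profile stays inside the lumen.
* `tcpcPhantom()`: a four-limb junction (SVC above, IVC below, RPA/LPA
  lateral) of rectangular channels extruded in depth. The in-plane field
  derives from a piecewise stream function: each (inlet, outlet) stream is
  a triangular corner-turn region carrying a constant oblique velocity
  whose normal components match the adjoining plug limbs, and the four
  triangles provably tile the confluence without overlap for any feasible
  split fractions. Consequences: the field is exactly divergence-free
  within each depth slab (plane-flux mass closure on the phantom is at
  machine precision), and the prescribed IVC→LPA / SVC→RPA split fractions
  are *exact* routing ground truth — a uniformly seeded caval section sends
  exactly that fraction of lines to each artery. A parabolic profile across
  the extruded depth adds a no-slip direction. This construction was chosen
  over distance-weighted blending of limb fields precisely because blending
  gives no control over where streamlines actually go, which is the
  quantity under test.
* `addVelocityNoise()`: i.i.d. Gaussian noise per component per voxel
  inside the dilated lumen, emulating VENC-dependent velocity noise;
  deterministic per seed.

What the phantoms deliberately do not emulate: Navier–Stokes secondary
flows, wall compliance, respiratory variation, phase-wrap aliasing, eddy
currents, and the plug profile has no no-slip layer across the routing
axis. Passing tests therefore demonstrate that the estimators are correct
on fields whose truth is known — quadrature, interpolation, integration,
gradients, routing, statistics — not that clinical acquisitions are free of
acquisition-physics artifacts, which are out of scope upstream of the mask
and field inputs.

Two phantom-level numerical facts worth knowing:

* Rectangular plug-profile channels carry a ~5% staircase overshoot in
  absolute plane flux at 1 mm resolution (the half-voxel ramp at the
  channel wall integrates as extra area). It cancels in mass-closure and
  split checks, and the smooth-profile Poiseuille phantom is the absolute
  flux oracle (where the error is ~0.5%).
* The EL/KE radius-scaling check compares tubes of radius 10 and 5 mm at
  resolutions scaled with the geometry (1 and 0.5 mm), so both carry equal
  relative discretization and the comparison isolates the \(R^{-2}\) law
  rather than the boundary-layer truncation error, which at a fixed 1 mm
  grid would contribute about -7% to the ratio. The absolute accuracy of
  EL at 1 mm is checked separately against the closed form.

## Cohort statistics

The statistics layer mirrors a clinical cohort analysis:

* `partialCorrelation()`: Pearson correlation of the residuals of x and y
  after regression on the adjusters (age-adjusted when the adjuster is
  age); p from the t distribution with \(n - 2 - k\) df; pairwise-complete
  cases per analysis (CPET variables exist only in a subgroup). With no
  adjusters it reduces to plain Pearson.
* `leveragePoints()`: hat values of the design \([1, z, x]\); cases with
  \(h_i > 3\bar h\) are dropped in a single pass. "Three times the mean
  leverage" is read as the standard hat-value rule; \(\bar h = (k+1)/n\)
  analytically, so the threshold is \(3(k+1)/n\). Whether to apply the
  exclusion is a per-analysis flag, since published practice applies it
  selectively (e.g. to NT-proBNP analyses).
* `compareGroups()`: Student's pooled-variance t-test (named choice;
  Welch behind a flag), with mean ± SD per group formatted as in cohort
  tables.
* `compareCorrelations()`: Fisher z-test,
  \(z = (z_1 - z_2)/\sqrt{1/(n_1-3) + 1/(n_2-3)}\).
* `summarizeVariable()`: mean ± SD or median (25th, 75th percentile) with
  linear-interpolation quantiles.
* No multiple-testing correction by default (alpha = 0.05 throughout, as
  is conventional in this literature); `p.adjust` can be applied to the
  tidy output of `cohortAnalysis()` if desired.

`syntheticCohort()` generates covariate tables with a planted age-adjusted
EL/KE vs peak-VO2 partial correlation (default -0.453 at the published
cohort scales: age 22 ± 10 y, peak VO2 20 ± 4.9 ml/kg/min, EL/KE near
0.24). `associationPower()` measures the Monte-Carlo power to recover the
planted association (two-sided p < 0.05 with the correct sign) over
replicate cohorts of the CPET subgroup size n = 34.

## Problem sizes and determinism

The validation suite runs on: a 27 x 27 x 41 tube at 1 mm (12,997 lumen
voxels; 53 x 53 x 41 at 0.5 mm for the radius-scaling pair), a
97 x 17 x 97 junction at 1 mm, 2,000 streamline seeds per caval
distribution, and 500 replicate cohorts of n = 34 for the power estimate.
Every stochastic stage (seeding, noise, cohorts) takes an explicit integer
seed and restores the caller's RNG state, so identical seeds give
bit-identical results; pipeline outputs are invariant under subject
reordering because subjects are processed independently under the same
seed.

## Known limitations

* WSS carries a systematic ~-13% bias at 1 mm/0.5 mm-raster resolution from
  near-wall interpolation; it is fit for sectional means and group
  contrasts, not absolute wall maps.
* Eccentricity and WSS assume near-convex lumen sections (radial wall
  normals); highly lobed sections would need contour-based normals.
* The energy-loss estimator omits divergence-penalty terms and inherits
  one-sided gradients at the wall; at 1 mm it sits a few percent below the
  Poiseuille closed form, converging from below as the grid refines.
* The junction phantom's plug inlet makes count-based and flux-based
  splits coincide; on real profiles uniform seeding undercounts the fast
  core relative to true flow fractions — `seedWeighting = "flux_weighted"`
  exists for that case, but uniform remains the default because published
  streamline percentages follow line-count semantics.
* NIfTI support assumes axis-aligned affines; oblique acquisitions must be
  resampled upstream.
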