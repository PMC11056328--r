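# fontanflow

Hemodynamic quantification of the Fontan (total cavopulmonary connection,
TCPC) circulation from segmented 4D-flow CMR velocity fields.

Patients with a single functional ventricle live with systemic venous
blood routed passively into the pulmonary arteries. How efficiently that
passive pathway carries flow — how caval streams distribute between the
pulmonary branches, how much kinetic energy the flow has and how fast
viscosity burns it, how skewed the conduit jet is — is measurable from a
single 4D-flow CMR acquisition and is clinically informative. This package
implements the full quantification chain for researchers working with
segmented 4D-flow data (velocity volumes + lumen masks), plus the analytic
flow phantoms needed to validate every stage against known ground truth.

## What it computes

* **Plane fluxes** (`planeFlux`): net flow in l/min through oriented
  vessel cross-sections, by sub-voxel rasterization and trilinear
  interpolation; indexed flows and mean section velocity.
* **Derived circulation parameters**: systemic-to-pulmonary collateral
  flow `QSPC = (Q_LPV + Q_RPV) − (Q_RPA + Q_LPA)` (`qspc`), effective
  cardiac index `(Q_Ao − QSPC)/BSA` (`effectiveCi`), and RPA/LPA flow
  asymmetry classification (ratio > 1.56 RPA-dominant, < 0.75
  LPA-dominant; `classifyAsymmetry`).
* **Streamline caval distribution** (`traceStreamlines`,
  `classifyOutlets`, `cavalDistribution`): adaptive Runge–Kutta 4(5)
  tracing from SVC/IVC seed planes; percent of resolved lines reaching
  each pulmonary artery.
* **Flow energetics** (`kineticEnergy`, `energyLoss`, `energetics`):
  voxel-level ½ρ|v|² and viscous dissipation 2μ e:e from mask-aware
  strain rates, integrated over a volume of interest and volume-normalized
  (µJ/ml, µW/ml), plus the EL/KE flow-efficiency index (1/s).
* **Section shape metrics** (`sectionShape`): sectional mean wall shear
  stress, flow jet angle and flow eccentricity.
* **Phantoms** (`poiseuillePhantom`, `tiltedJetPhantom`, `tcpcPhantom`,
  `addVelocityNoise`, `syntheticCohort`): analytic fields with attached
  closed-form or exact ground truth for every estimated quantity.
* **Cohort statistics** (`partialCorrelation`, `leveragePoints`,
  `compareGroups`, `compareCorrelations`, `summarizeVariable`,
  `cohortAnalysis`): age-adjusted Pearson partial correlations with
  hat-value leverage exclusion, Student's t group comparisons, Fisher
  z-tests between correlations.

IO: velocity fields and masks in NIfTI or HDF5, planes and pipeline
configs in YAML, cohort tables in CSV (`readVelocityField`,
`readLumenMask`, `readPlanes`, `runPipeline`). A thin command-line front
end ships in `inst/exec/fontanflow` (`run`, `phantom`, `stats`).

## Worked example

```r
library(fontanflow)

## a straight-tube phantom: R = 10 mm, centerline 60 cm/s, 1 mm grid
ph <- poiseuillePhantom(radius = 10, length = 40, vmax = 60)
groundTruth(ph)$qLmin
#> [1] 5.654867

planeFlux(ph@field, ph@mask, ph@planes$tube)
#> FlowResult 'tube': qNet 5.625 l/min, mean velocity 29.6 cm/s, 1 phase(s)

en <- energetics(ph@field, ph@mask, voiFromSegments(ph@mask, "tube"))
en
#> EnergeticsResult: KE 63 uJ/ml, EL 24.3 uW/ml, EL/KE 0.385 1/s (VOI 13.0 ml)
#>    164 voxel(s) excluded from the EL integral (isolated on some axis)
```

The measured flux sits within 0.5% of the closed form
`vmax·πR²/2 = 5.655 l/min`; the energetics land within a few percent of
`ρ vmax²/6 = 63.6 µJ/ml`, `2μ vmax²/R² = 25.2 µW/ml` and
`12μ/(ρR²) = 0.396 s⁻¹` — the residuals are boundary-layer discretization
at 1 mm resolution.

```r
## a TCPC junction phantom routing 75% of IVC flow to the LPA
tc <- tcpcPhantom(splitIvcLpa = 0.75, splitSvcRpa = 0.9)
sl <- cavalDistribution(tc@field, tc@mask, tc@planes$IVC,
                        nSeeds = 2000, seed = 1)
distribution(sl)
#>      RPA      LPA
#> 25.65076 74.34924
```

2,000 uniformly seeded IVC streamlines reach the LPA 74.3% of the time
against an exact routing truth of 75% (binomial seeding noise ±1%,
interface discretization ±1–2 points).

```r
## cohort layer: planted age-adjusted EL/KE vs peak-VO2 association
d <- syntheticCohort(n = 34, rPartial = -0.453, seed = 1)
partialCorrelation(d$elKeIndex, d$vo2Peak, d["age"])
#> Partial correlation adjusted for age: r = -0.428, t(31) = -2.64, p = 0.01292, n = 34
```

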