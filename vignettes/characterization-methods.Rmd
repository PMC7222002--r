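---
title: "Models and methods for semi-solid characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for semi-solid characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ointchar)
```

This vignette documents the models behind each analysis stage, the
parameters that matter, the numerical choices made where the procedure is
conventionally under-specified, and what the synthetic-data generators do
and do not emulate.

## Spreadability

The parallel-plate test presses a fixed ointment volume between glass
plates under stepwise-increasing load and reads the sample diameter after
each step. Diameters become circle areas, areas are averaged over
replicates per load (the protocol uses n = 5), and the mean areas are
fitted by ordinary least squares to the logarithmic spreading law

$$\mathrm{area}(x) = a\,\ln x + b,$$

where $x$ is the **total** applied mass. Two conventions are possible for
$x$ — added weights only, or plate plus weights — and the test protocol
(298 g plate, 20–500 g of added weights) makes them differ substantially.
We take $x$ as the total mass: integrating fitted curves over the total
range 298–798 g reproduces independently reported area-under-curve values
for this formulation series to better than 1%, while the added-mass
convention does not.

The area under the spread curve is by default the closed-form integral of
the fitted law,

$$\mathrm{AUC} = \int_{x_0}^{x_1} (a \ln x + b)\,dx
  = \big[a(x\ln x - x) + bx\big]_{x_0}^{x_1},$$

over the load range, with a trapezoid-on-raw-means variant
(`method = "trapezoid"`) for when the raw data rather than the fit should
carry the answer; on dense, clean data the two agree to 0.1%. The
spreadability index $i(S) = \mathrm{AUC}_{test}/\mathrm{AUC}_{ref}$ is
rounded to 3 decimals for reporting, matching how such indices are quoted
(coefficients to 3 decimals, AUC to 1).

Replicates are averaged **before** fitting, since reported coefficients for
this kind of test are fits to per-load means; fitting per replicate and
pooling is possible by calling `fit_log_spread()` per replicate subset.

## Rheology

`summarize_step_viscosity()` reduces replicate readings at fixed shear
rates (300, 700, 1100 s⁻¹ in the standard protocol) to mean ± sample SD
per formulation × temperature × rate cell, and flags shear thinning when
mean viscosity falls monotonically with rate. Cells with a single replicate
are an error rather than a silent SD of NA: a bench summary without
replication is not a summary.

### Yield-stress fits

Two parameterizations of the yield-stress flow model are implemented:

* `"linear"` (default): $\tau = \tau_y + \eta\dot\gamma$, fitted by OLS on
  the ascending branch. Algebraically this is the Bingham plastic form; it
  is also the linearized form in which Casson-type fits of semi-solid flow
  curves are often quoted, which is why it is the default.
* `"square_root"`: the conventional Casson law
  $\sqrt\tau = \sqrt{\tau_y} + \sqrt{\eta\dot\gamma}$, linear in
  $\sqrt{\dot\gamma}$ after transformation.

In both, $\tau_y$ is clipped at zero (a negative yield stress is a fitting
artifact, not a material property) and R² is reported on the untransformed
stress scale so the two variants are comparable.

### Thixotropy

The hysteresis loop between the ascending and descending shear ramps is
integrated on the rate–stress plane: the descending branch is linearly
interpolated onto the ascending branch's rate grid, restricted to the
overlapping rate interval, and $\int (\tau_{up} - \tau_{down})\,d\dot\gamma$
is taken by the trapezoidal rule. The ascending grid is the natural common
grid because the ascending ramp probes the undisturbed structure. Loop
areas on the rate–stress plane (Pa/s) are the quantity rheograms display;
integrating on stress–time axes would weight the two branches by dwell time
instead. For smooth branches the trapezoidal result is stable under 2×
denser resampling to well under 0.5%.

Sign convention: positive area (ascending above descending) is thixotropic
breakdown; negative area is flagged anti-thixotropic; |area| below a small
tolerance is reported as reversible. The 15 s pre-shear at 100 s⁻¹ that
precedes the ramp is simulated by the generator but is metadata to the
fits — it standardizes the starting structure and plays no role in the
least squares.

## Texture profile analysis

A TPA trace holds two compression episodes separated by a pause. Episodes
are detected as runs of at least 3 consecutive samples above the 0.01 N
trigger force (the debounce suppresses single-sample noise crossings), and
each onset/offset is then **refined to the interpolated zero-force
crossing**. The refinement matters: a pure threshold crossing starts the
episode late by `trigger/slope` seconds, which biases the compression
travel of a soft second peak by over 1% — more than the package's own
round-trip tolerance — whereas the interpolated onset is exact for locally
linear force ramps.

Extracted parameters:

* hardness — peak force of episode 1 (N);
* cohesiveness — ratio $A_2/A_1$ of positive-force **time** integrals: the
  conventional definition is on the force–time curve, so no speed enters;
* elasticity — ratio $D_2/D_1$ of compression travels, with
  $D = v_{descent} \times$ (onset-to-peak duration) when no displacement
  channel is available; a direct displacement channel, if the instrument
  exports one, should be preferred upstream;
* adhesion force — the global force minimum (≤ 0 by construction);
* adhesiveness — the magnitude of $\int F\,ds$ over the negative lobe
  after episode 1, with $ds = v_{ascent}\,dt$, reported in mJ (N·mm). The
  conversion through the ascent speed reconciles the time-domain trace with
  the work units in which adhesiveness is conventionally reported.

Tensile strength $F/A$ and Young's modulus $(F/A)/(\Delta l/l)$ require
the probe cross-section $A$ as configuration — probe geometry is
instrument-specific and must come from the user; examples in the package
use $10^{-4}\,\mathrm{m}^2$ as an illustrative placeholder only.

## Release kinetics

The enhancer-cell experiment loads ~1 g of ointment behind a membrane with
a 3.8 cm² orifice into a 50 mL stirred acceptor vessel at 32 °C; 3 mL
aliquots are withdrawn for UV assay at 15, 30, 60, 90, 120 and 150 min and
replaced with fresh medium. Each withdrawal removes analyte and each
replacement dilutes the vessel, so the cumulative amount released per unit
area is recovered by the standard mass balance

$$Q_n = \frac{C_n V + \sum_{i<n} C_i V_s}{A},$$

which exactly inverts the sampling procedure — a property the test suite
verifies against a forward simulation to $10^{-9}$, for any aliquot
volume.

Model forms and fitting choices:

* zero-order $Q = k_0 t$ and Higuchi $Q = k_H\sqrt t$ are through-origin
  least squares. The Higuchi fit is restricted to the 15–150 min window —
  the window over which this release protocol is conventionally modelled —
  and an intercept-allowed variant exists for diagnostics.
* first-order $Q = Q_\infty(1 - e^{-k_1 t})$ minimizes the SSE over $k_1$
  by golden-section search; a one-parameter search cannot fail to converge,
  unlike a general nonlinear fit on six points.
* Korsmeyer–Peppas is fitted on $\log(Q/Q_\infty) = \log k + n\log t$
  restricted to fractional release ≤ 0.6, the regime in which the power
  law is meaningful.
* Weibull is fitted on its exact double-log linearization; at $\beta = 1$
  it reduces to the first-order model, and the two fits agree on the rate
  to $10^{-6}$ on exponential data (a test).

$Q_\infty$ defaults to loaded dose / orifice area, because release in this
system approaches dose completion within the run; a profile-based maximum
is available by passing `q_inf` explicitly. R² is always computed about the
mean on the original $Q$ scale, so constrained fits can legitimately score
below zero and model ranking is fair across transforms.

Replicate rate estimates are compared with Welch's t-test (variances of
bench replicates differ visibly between formulations; the pooled variant
exists for convention's sake). No multiplicity correction is applied to the
pairwise tests and the report says so: with three formulations the
correction would be cosmetic, and uncorrected per-pair p-values are what
the downstream summary quotes.

## Synthetic instruments: what they emulate

The generators' defaults are the study conditions of the characterization
protocol: 5 replicates over 298–798 g in 20 g steps (spreadability),
100→1100→100 s⁻¹ ramps with 15 s pre-shear at two temperatures (rheology),
5 mm/s descent / 0.1 mm/s ascent / 10 mm depth / 0.01 N trigger (TPA), and
the 50 mL / 3 mL / 3.8 cm² / 6-time-point geometry at 32 °C (release).

* **Spreadability** adds Gaussian noise to the log-law areas and converts
  back to diameters. Default noise 0.5 cm² in the full-study driver: about
  2–3% of a typical area, consistent with reading a spreading diameter to
  ±0.1 cm.
* **Flow curves** use a structural-kinetics model: structure
  $\lambda \in [0,1]$ with
  $d\lambda/dt = -k_b \dot\gamma \lambda + k_r(1-\lambda)$ and
  $\tau = (\tau_y + \eta\dot\gamma)(\lambda_{floor} + (1-\lambda_{floor})\lambda)$.
  This is the simplest mechanism that produces the observed phenomenology:
  loops close when $k_b = 0$, open when $k_b > 0$, and shrink when $\eta$
  drops (the skin-temperature analogue). $\lambda_{floor} = 0.2$ keeps the
  stress from collapsing at full breakdown, as real semisolids retain a
  flowing matrix.
* **TPA traces** are piecewise linear and built so that extraction returns
  the requested profile identically: episode 1 is a symmetric triangle at
  the hardness, the detachment lobe is a triangle with the requested
  minimum and work, and episode 2's duration and peak encode elasticity
  and cohesiveness. Segment breakpoints are included in the sampling grid,
  making trapezoidal integrals of the noiseless trace exact.
* **Release experiments** simulate the vessel bookkeeping event by event
  and push concentrations through the calibration line. Photometric noise
  is **uniform** on ±0.005 A rather than Gaussian: an instrument accuracy
  specification is a bound, not a standard deviation. When the nominal
  kinetic law would release more than the loaded dose within the schedule,
  the generator caps the release at the dose and warns — the physical
  default. The exact-inversion validation runs set `cap_at_dose = FALSE`:
  their purpose is to verify the measurement chain (calibration inversion
  and withdrawal correction), and a rate constant quoted for a profile is
  by definition the through-origin fit of the uncapped law over the
  modelling window.

What the generators do **not** emulate: solvent evaporation and temperature
drift during spreading, viscous heating and slip in the rheometer, probe
inertia and sample fracture in TPA, and membrane transport or boundary
layers in release (release follows the phenomenological kinetic law
directly). Passing round-trip tests therefore demonstrates that the
analysis stages are mutually consistent and numerically correct — not that
real instruments are free of these effects. Real traces with fracture
events or drifting baselines will need upstream cleaning before
segmentation.

## Statistical conventions and problem sizes

Means are arithmetic, SDs are sample SDs (n − 1). Welch's test handles the
zero-variance degenerate cases explicitly (equal constant groups: t = 0,
p = 1; different constant groups: p → 0 limit). Pearson correlations come
with the usual caveat that values computed from per-formulation summary
statistics generally differ from values computed on raw replicates; the
package computes whatever it is given, and its tests freeze the
summary-table value.

The test suite and the study driver run at the protocol's own scale
(5 replicates, 26 load steps, 21-point ramps, 20 Hz TPA traces, 6 release
time points, a few hundred simulated tests for power checks); a full run
of everything completes in well under a minute on one core.

## Known limitations

* Casson R² values from the two variants are comparable but the linear
  variant will fit genuinely square-root data with a small positive bias in
  $\tau_y$; choose the variant to match the physics, not the R².
* Hysteresis areas from ramps with very few points (< 10 per branch)
  inherit trapezoid error of a few percent; the generators default to 21
  points per branch.
* `fit_release_model()` assumes cumulative, non-decreasing profiles;
  strongly non-monotone (noisy) profiles trigger a warning at the
  correction step rather than being silently smoothed.
* The TPA segmentation expects a flat near-zero baseline between episodes;
  baseline drift must be removed upstream.
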