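---
title: "Models and methods for small-field proton dosimetry simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for small-field proton dosimetry simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braggdose)
```

## Purpose and scope

braggdose evaluates the dosimetric behavior of small proton radiosurgery
fields at desk scale. Everything a water tank, a beamline, and a Monte
Carlo nozzle model would provide is replaced by parametric generators that
are calibrated to the same summary quantities a physicist would commission
against: the distal D50, the distal 80–20% falloff, the modulation width,
and the lateral field widths at reference depths. On top of the generators
sit detector models (sensitive-volume footprints, window bookkeeping,
charge readout) and the extraction and comparison analyses themselves,
which are the part intended to be reused on real measured profiles.

It follows that the package separates cleanly into what is *simulated*
(beams, event samples, charge readouts — stand-ins) and what is *analyzed*
(metrics, moments, fits — real methods). Tests exercise the analyses
against closed forms and dense-evaluation oracles independently of the
generators wherever possible.

## The pristine peak model

The depth-dose curve of an unmodulated beam is built from a residual-range
power law, cell-averaged on a 0.02 mm internal grid and convolved with a
Gaussian range-straggling kernel:

$$ d_0(z) \propto (R_0 - z)^{-0.435} + \beta\,(R_0 - z)^{0.565},
   \qquad z < R_0 $$

The first term captures the steep rise of stopping power near the end of
range; the second sets the entrance plateau. With $\beta = 0.005$ per mm
the entrance-to-peak ratio is about 0.31, typical of a scattered beam with
substantial energy spread. The two free parameters $(R_0, \sigma)$ are not
exposed to the user: they are solved by fixed-point iteration (typically
4–6 curve evaluations) so that the *convolved* curve has exactly the
requested distal D50 and 80–20% falloff. This parameterization-by-
observables was chosen because an energy-to-range conversion cannot
reproduce a particular beamline's energy loss, whereas D50 and falloff are
what a clinic actually measures.

Default falloffs scale with range: 3.5 mm at D50 = 99.5 mm and
proportionally elsewhere (5.5 mm at 153 mm). The value is chosen so the
distal 95→25% width of the calibrated curve is ≈ 4.3 mm, which places the
dose-ratio change induced by a 0.4–0.9 mm detector misalignment in the
10–30% band expected for these beams (see *Shift sensitivity* below). A
4 mm falloff would widen the 95–25% span to ≈ 5 mm and push the 0.4 mm
sensitivity just below that band.

## SOBP synthesis

A spread-out Bragg peak is a non-negative weighted sum of range-shifted
copies of the calibrated pristine peak at a nominal 2 mm pullback spacing.
Weights solve a least-squares problem against a flat unit target on the
plateau, augmented with a small second-difference penalty
($\lambda = 0.05$) on the weight vector — plain non-negative least squares
produces physically implausible alternating weights (ringing) with no
better plateau. Because the 90% crossings sit outside the outermost
component peaks, a plateau spanning exactly the modulation width requires a
*smaller* pullback span; the span is iterated (converges in 2–4 steps)
until the measured proximal-90% to distal-90% extent equals the requested
modulation. Achieved extents for 15/30/60 mm modulation are within 0.2 mm
and plateau deviation is below 1.7%; a plateau deviation above the 2%
tolerance raises a diagnostic error rather than returning a bad beam.

**Flatness convention.** The 90–90% region necessarily contains the
0.9 → 1.0 edge ramps, so flatness over the *whole* region would be ~7% for
any physical SOBP. Flatness is therefore reported over the plateau
interior: the 90–90% region trimmed at each edge by max(10% of the extent,
two pullback steps) and, during synthesis, further restricted to the
designed flat-target span. Modulation width itself is *defined* as the
proximal-90% to distal-90% extent.

## Lateral model and dose grids

Transverse profiles use an error-function aperture edge,
$D(x) = \Phi\!\big(\tfrac{a-x}{\sigma}\big) + \Phi\!\big(\tfrac{a+x}{\sigma}\big) - 1$
with $a$ the aperture radius and $\sigma(z) = \sigma_0 + g z$
($\sigma_0 = 0.7$ mm, $g = 0.004$). These defaults put the 20 mm aperture's
FW90M at 33 mm depth at 17.9 mm and its FWHM at 20.0 mm, consistent with
the reference widths for these fields. The closed forms
FW90M $= D - 2 z_{0.9}\sigma$ and penumbra $= (z_{0.8}-z_{0.2})\sigma
\approx 1.683\sigma$ serve as test oracles.

Dose grids are the separable product $P(z)\,L(x,z)\,L(y,z)$ on a 0.5 mm
isotropic lattice (beam along +z, voxel centers at half-integer spacing,
0-based indices, z slowest when serialized). Central-axis depth profiles
average the four central voxel columns. A request above $10^8$ voxels is
refused before allocation.

## Event sampling and lineal energy

Each scoring slice is 20×20 voxels of 0.05 mm × 0.02 mm thickness; the
mean chord length is taken equal to the thickness (20 µm), so lineal
energy is simply $y = \varepsilon / \bar l$ and the 400 voxels collectively
match the diode's sensitive volume. Per-voxel event counts are Poisson
with rate $n\,F(z)/400$, where the relative fluence $F(z)$ declines
linearly to 80% of entrance at the peak (a nuclear-removal stand-in) and
then through the straggling sigmoid. Event energies mix a Gamma primary
component (shape 5) with an exponential heavy tail of 10× the primary mean
whose weight rises smoothly from 2% at entrance to 15% beyond the distal
90% depth; the mixture is rescaled so the *overall* mean of $y$ equals the
configured depth-dependent mean exactly, which keeps the entrance
calibration honest while the tail drives the sharp distal rise of
$\bar y_D$. The moments are computed as sample sums, the consistent
estimator of the single-event density integrals; a histogram-based
estimate would only add binning error. Slices with fewer than 100 events
warn rather than fail, since distal slices are naturally event-poor, and a
slice beyond all fluence returns an empty, flagged event set.

These choices reproduce the qualitative microdosimetric behavior
(monotone $\bar y_D$ rise, sharp distal increase) but are not
track-structure physics: no event spans voxels, no secondary-particle
spectrum is modeled, and absolute $\bar y_D$ values are stand-ins.

## Detector models

Footprints are uniform: a disc of radius 0.564 mm (1 mm² cross-section)
for the axial diode, radius 2.65 mm for the chamber, and a
0.02 × 1.128 mm rectangle for the edge-on diode, whose scan-direction
extent is the 20 µm sensitive-volume thickness. Volume averaging uses a
quadrature grid of at most 0.01 mm across the footprint (scans of
separable analytic fields factor the average, so the chamber's ~200k-node
footprint costs one outer product per position). Depth scans report at the
effective depth, stage + water-equivalent window (1.33 mm diode, 1.06 mm
chamber); the `report = "stage"` mode mimics uncorrected tank software and
reproduces the 0.27 mm D50 offset between the two detectors.

The edge-on sensitive volume is centered at the stated scan depth — no
edge-on window thickness is specified by the manufacturer, and centering
the volume is the practice that makes the two orientations agree. The
axial size-effect rule of thumb, deviation ≈ 0.5·r with an edge-on/axial
ratio of 0.03, is implemented as a reporting function (axial values
rounded to one decimal mm, matching the convention in which 0.282 is
quoted as "0.3 mm"). The scan-based broadening matches 0.5·r only in the
sharp-edge regime ($\sigma \lesssim 0.3 r$); for a Gaussian edge of width
$\sigma$ the broadening is $1.683(\sqrt{\sigma^2 + r^2/4} - \sigma)$,
which the tests verify against dense numeric integration.

The charge readout is
$Q = S\,D\,(1 - \lambda A)\,k_{\text{orient}}\,k_{\text{LET}}(1+\epsilon) + Q_0$
with sensitivity $S$ (default 3.3 nC/Gy), offset $Q_0 = 100$ pC, decay
$\lambda = 10^{-4}$/Gy, orientation factor 0.994 (edge-on only), optional
LET over-response $k_{\text{LET}} = 1 + c\,\max(0, y - y_0)$ (disabled by
default — the diode's LET dependence is negligible up to the very distal
SOBP, and the toggle exists to reproduce distal ratio rises), and
multiplicative Gaussian noise $\epsilon$ (default 0.5% relative; the
reference data report error bars but no noise model). There is no
dose-rate term: uniformity with dose rate holds by construction, and the
uniformity analysis exists to *verify* that on synthetic data. Note the
offset is part of measured charge/MU, so the orientation difference
computed from raw ratios (≈0.59% at factor 0.994) is slightly diluted
relative to the signal-only difference (0.6%) — exactly as it would be in
the real experiment.

## Comparison analyses

Ratio curves resample the diode profile onto the reference grid by local
quadratic (three-nearest-sample Lagrange) interpolation — the reference
workflow calls for second-order interpolated ratios — and are clipped at
the reference's distal 25% dose. Distal-edge ratios are evaluated at the
reference's 90% and 95% distal crossings. Shift sensitivity assumes a
linear dose falloff between the 95% and 25% crossings and evaluates the
ratio change at the mid-falloff (60%) level: $\Delta = s\,g/0.6$ with
$g = 0.7/(z_{25}-z_{95})$. The averaged gradient understates the local
slope at 60% by ~20% (the falloff is not exactly linear); the tests pin
both the band (10–30% for 0.4/0.9 mm shifts) and the relation to direct
evaluation.

Calibration fits are ordinary least squares throughout, with t-based
confidence intervals at the experiment's replicate counts (≤10
replicates); the decay slope is rescaled to % per 100 Gy. The
dose-rate verdict is "uniform" when the slope CI covers zero — a 95%
interval, so over many seeds roughly 5% of null runs report a trend, and
the tests assert nominal coverage within binomial slack rather than an
exact rate.

## Problem sizes and determinism

Default problem sizes are chosen so every analysis runs interactively:
$10^4$–$10^5$ primaries per microdosimetry slice, 200-run
parameter-recovery ensembles, 0.25–0.5 mm scan steps, 0.5 mm dose-grid
voxels. All stochastic functions take an explicit integer seed and draw
from a locally seeded generator (no global RNG state is touched);
per-depth and per-set seeds are derived deterministically with spacing
that keeps ensemble runs independent. Identical seeds give byte-identical
outputs.

## Known limitations

* No transport physics: the fluence ramp, stopping-power stand-in and
  secondary tail are calibrated shapes, not cross sections; conclusions
  about real detectors require real measurements.
* The lateral model is separable in x and y, so corner regions of the
  field are slightly sharper than a true circularly collimated field.
* Pristine peaks synthesized into an SOBP share one shape; a real
  modulator wheel sees slightly sharper shallow peaks.
* The 25% distal clip, the 60% shift-sensitivity level, and the COM
  definition (midpoint of the 90–90% bounds) are conventions; they are
  stated here because alternatives exist in other tank software.
* Film dosimetry, 2-D dose maps, gamma analysis, ion-recombination and
  semiconductor physics are out of scope.
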