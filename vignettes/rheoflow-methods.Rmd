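---
title: "Measuring blood microrheology in a co-flow microchannel: models and methods"
author: "rheoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring blood microrheology in a co-flow microchannel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rheoflow)
```

# The measurement problem

Red blood cells (RBCs) in plasma aggregate reversibly into rouleaux
("stacks of coins") and larger three-dimensional clusters.  Aggregation is
strongest at low shear rates (roughly 1–50 s^-1^) and is the main reason
dilute blood is shear thinning: apparent viscosity falls as shear rises and
aggregates break up.  Quantifying this microrheology calls for three linked
measurements inside one microchannel:

1. **apparent viscosity** of the suspension at a known shear condition,
2. **the shear rate** actually experienced by the suspension, and
3. **aggregate sizes** under those same conditions.

`rheoflow` implements this measurement chain for a co-flow ("optical
viscometer") configuration: blood enters one branch of a Y-junction and is
entrained by a faster, more abundant reference stream (a saline buffer)
entering the other branch.  The two streams flow side by side down a
rectangular channel — 110 μm wide and 60 μm deep by default — and the
position of the interface between them encodes the viscosity contrast.

Because raw recordings of human blood are not distributable, the package
pairs every analysis stage with a seeded synthetic generator that produces
the same kind of input (velocity fields, tracer-particle image pairs,
bright-field aggregate frames, viscosity curves) together with machine-
readable ground truth.  All quantitative claims in the test suite are made
against that truth.

# Two-fluid stratified duct flow

## Model

Both streams obey the axial momentum balance for fully developed laminar
flow,

$$\mu_k \left(\partial_y^2 + \partial_z^2\right) u_k = -G, \qquad k = 1, 2,$$

with a common pressure gradient $G$, no-slip walls, and a flat interface at
the dimensionless transverse position $Y \in (-1/2, 1/2)$ (measured from
the channel centerline across the width $w$; $Y = 1/2 - w_1/w$ where $w_1$
is the reference-stream width).  At the interface the velocity and the
shear stress $\mu\,\partial_y u$ are continuous.  Integrating $u$ over each
stream's cross-section gives the central result of comparator viscometry:
the flow-rate ratio $Q_1/Q_2$ depends only on the viscosity ratio
$\mu_2/\mu_1$, the interface position $Y$, and the aspect ratio
$\beta = h/w$.  With the pump-imposed $Q_1/Q_2$ and an observed $Y$, the
relation inverts to the unknown apparent viscosity $\mu_2$.

Assumptions worth stating: the interface is a flat vertical plane (good
when interfacial tension and inertia are negligible — the Reynolds number
in these channels is of order 10^-2^); the two fluids do not mix
appreciably over the measurement length; the flow is steady and fully
developed at the measurement station.

## Numerical evaluation

`seriesFlowRatio()` evaluates the classical Fourier-series solution mode by
mode across the channel depth (odd modes $\cos(n\pi z / h)$).  Two choices
keep the evaluation robust:

* The plane-Poiseuille part of each stream's profile, whose flow-rate
  contribution is $G h^3 d_k / 12\mu_k$ in closed form, is split off; the
  remaining per-mode harmonic corrections are obtained from a 4×4 linear
  system per mode and decay like $n^{-5}$.
* Each mode's correction is expressed in a basis of exponentials with
  non-positive arguments, never as raw `sinh`/`cosh` ratios, so nothing
  overflows however extreme the aspect ratio.

Truncation stops when one more term changes both partial flow sums by less
than `relTol` (default 10^-12^), or at `maxTerms` (default 400 odd terms,
which reaches that tolerance everywhere in the validated parameter region;
a truncation that ends further than 10^6^ × `relTol` from convergence
raises an error carrying the last two partial values).

Inversions (`solveViscosityRatio()`, `solveInterfacePosition()`) verify
monotonicity of the forward map numerically and then use a bracketing root
finder on a log scale; brackets are $[10^{-3}, 10^3]$ for the viscosity
ratio and $[-0.499, 0.499]$ for the interface.

## The independent cross-check

`fdVelocityField()` solves the same boundary-value problem by a
conservative second-order finite-difference scheme with face viscosities
evaluated at face midpoints, so the interfacial stress condition is
built into the flux balance; the interface is snapped to the nearest grid
line.  The two solvers share no code and agree to well under 1% on a
201×201 grid across viscosity ratios 0.2–20 and interface positions
±0.3 — this mutual agreement, together with exact symmetry
($Q_1/Q_2 = 1$ when the fluids and widths match) and monotonicity, is what
pins down sign and grouping conventions in the series.  The finite-
difference field is also the velocity source for the synthetic particle
images, which keeps the oracle and the generator consistent.

# Micro-PIV velocimetry

Tracer-particle image pairs are interrogated by normalized FFT
cross-correlation in two passes (64² then 32² px windows, 50% overlap);
coarse-pass displacements, validated and rounded, shift the second-pass
windows of the second frame.  Methodological details that matter:

* **Anisotropic window weighting.**  Windows are weighted by a Gaussian
  elongated 4:1 along the flow before correlation.  This sharpens the
  transverse localization of each vector — important when the quantity of
  interest is a transverse velocity gradient.
* **Envelope normalization.**  Weighting multiplies the correlation plane
  by the weight autocorrelation, a lag-dependent envelope that biases
  uncompensated displacements toward zero.  The plane is divided by that
  envelope, and lags where the envelope retains under 5% of its peak are
  excluded as unmeasurable.
* **Sub-pixel peak.**  Three-point Gaussian interpolation in each axis.
* **Validation.**  The normalized median test (threshold 2, 3×3
  neighborhood) flags outliers, which are replaced by local medians and
  marked, never silently.  Fields are padded by *linear extrapolation*
  before the test: in a strong shear gradient a one-sided neighborhood
  (mirror or replicate padding) would systematically flag and overwrite
  correct wall-row vectors with faster interior values, biasing the
  near-wall profile — the single largest error source we found in
  end-to-end trials.
* **Signal gating.**  Windows whose intensity energy falls below 10% of
  the 95th-percentile window energy contain no tracers (for example on the
  unseeded reference-stream side); their noise peaks are discarded rather
  than validated.  Windows whose displacement compensation would run off
  the frame edge are likewise dropped in the refinement pass.

Velocities follow from the exact scaling $v = d \cdot \alpha_c / \Delta t$
(px × μm px^-1^ / ms = mm s^-1^).  Repeated fields are averaged per grid
point over time; the root-mean-square fluctuation
$\sqrt{(N\sum u_i^2 - (\sum u_i)^2)/(N(N-1))}$ — algebraically the sample
standard deviation — is attached per point before streamwise averaging
produces one representative transverse profile.

The blood layer is located from the transverse tracer-density profile
(tracers are seeded in the blood only): the maximal contiguous band above
half the peak density, with edges refined by linear interpolation of the
threshold crossing.  The shear rate is the ordinary-least-squares slope of
the profile over the central 80% of that band (avoiding wall and interface
bias), converted to s^-1^.  The synthetic truth records the same windowed
slope evaluated on the exact mid-depth profile, so estimator and truth
share one definition.

# Aggregate detection and sizing

Bright-field frames show aggregates as dark objects on a bright
background.  The chain is: illumination correction → global threshold →
hole filling → minimum-area filter → connected-component labeling → areas
in μm².

* **Illumination correction** divides the frame by a Gaussian-blurred
  background estimate (scale 50 px, far above a cell) and renormalizes to
  the original median.  The frame is padded by odd (anti-mirror)
  reflection before blurring, which continues linear illumination trends
  through the border: a pure ramp is corrected to a constant exactly, and
  a ramp-lit object segments completely where the uncorrected frame fails.
* **Thresholding** uses Otsu's method on the corrected frame by default
  (a fixed threshold is available).  Otsu always splits a histogram, so on
  an object-free frame it would segment noise; the threshold is therefore
  capped at five robust noise widths (MAD) below the background median,
  which keeps blank frames blank without affecting frames that contain
  objects.
* Objects smaller than 20 μm² (about one projected RBC) are discarded;
  components are 8-connected; border-touching objects are kept by default.
  No distinction is made between rouleaux and 3-D clusters, and no
  tracking links frames.

Per-frame mean areas are averaged into a recording mean (mean of per-frame
means, empty frames excluded and counted), with the standard error taken
over per-frame means; repeated recordings are combined the same way one
level up.  Size classes default to {0, 100, 500, 1500, 3500, ∞} μm²,
bracketing single cells, small and large rouleaux, and clusters.

# Rheological model fitting

Two shear-thinning laws are fitted to (shear rate, apparent viscosity)
curves:

* **Power law** $\mu = K \dot\gamma^{\,n-1}$ — fitted by ordinary least
  squares of $\log\mu$ on $\log\dot\gamma$ (slope $n-1$, intercept
  $\log K$).  $K$ carries the viscosity unit of the curve times
  s^n-1^; no silent unit conversion is applied.
* **Carreau** $\mu = \mu_\infty + (\mu_0 - \mu_\infty)
  (1 + (\lambda\dot\gamma)^2)^{(n-1)/2}$ — fitted by Levenberg–Marquardt
  with $\mu_0, \mu_\infty, \lambda$ log-transformed for positivity, and
  the data-driven start $\mu_0 = \max\mu$, $\mu_\infty = \min\mu$,
  $\lambda = 1$ s, $n = 0.5$.  Any parameter can be held fixed (relaxation
  times cluster tightly across fitted conditions in practice, so a
  fixed-λ refit is one click); the RMSE degrees of freedom shrink
  accordingly.

Goodness of fit is always reported as both R² (on the linear viscosity
scale — R² is of limited value for nonlinear fits, so it never stands
alone) and the degrees-of-freedom-corrected RMSE
$\sqrt{\sum(\mu_{exp}-\mu_{fit})^2/(m-p)}$.  A negative fitted index
attaches a warning rather than an error: shear ranges that only sample the
upper plateau region can produce one legitimately.

A note on identifiability: with shear sampled in [0.5, 100] s^-1^ and
relaxation times around 3 s, the infinite-shear plateau lies mostly outside
the window, so $\mu_\infty$ and $\lambda$ absorb disproportionate noise —
at 2% multiplicative noise their recovery error can reach ~15–25% while
$\mu_0$ and $n$ stay within 10%.  The tests encode exactly that
expectation; on noiseless data all four parameters return to machine or
solver precision.

# What the synthetic data do and do not emulate

The generators reproduce the study conditions: a 110 × 60 μm channel, the
reference stream at four times the blood flow rate, blood flow rates of a
few to a few tens of μL/hr giving blood-layer shear rates of order
1–50 s^-1^, tracer imaging at 0.27 μm/px with the inter-frame time chosen
for 6–10 px displacements, bright-field imaging at 0.2 μm/px, and object
shapes (disks, rouleaux chains of overlapping ellipses with 8 μm long
axes, connected cluster blobs) spanning ~100–8000 μm².  The reference
viscosity defaults to 1 cP as a generic saline-like value — it is a
generator setting, not an asserted property of any particular buffer.
Aggregate areas are drawn log-normally (meanlog log 300 μm², sdlog 0.6) —
a modeling choice; no claim is made about the real size distribution.

Deliberately not modeled: Brownian motion and depth-of-correlation effects
in PIV (tracers advect exactly with the local mid-depth velocity);
out-of-focus light, diffraction halos and RBC internal structure in
bright-field frames (objects are flat dark shapes with a 1 px soft edge);
aggregation kinetics (frames are statistically independent); interface
curvature and inter-stream diffusion.  Passing tests therefore demonstrate
that the *algorithms* recover known truth under controlled degradations
(noise, illumination gradients, crowding) — they do not certify
performance on real microscope recordings, where the unmodeled effects
add error.

A consequence of mid-plane rendering: at high packing fractions (the
higher-hematocrit proxy) objects are allowed to overlap, and the detector
visibly undercounts distinct objects — reproducing qualitatively the known
difficulty of separating aggregates in denser suspensions.

# Degenerate inputs and edge behavior

Blank frames segment to zero objects (not an error); recordings whose
frames are all empty summarize to `NA` with a flag; a single-frame
recording reports a standard error of 0 by convention.  All-zero tracer
density raises a detection error.  Power-law evaluation rejects zero shear
(the law diverges there); Carreau accepts it and returns $\mu_0$.
Inversion failures report the forward values at both bracket ends.
Series non-convergence reports the last two partial sums.

# Problem sizes used in the tests

The suite runs the finite-difference oracle at 101²–401², full PIV on
407 × 192 px frames with 2–8 pairs per case, and aggregate recordings of
25–200 frames at 300 × 640 px; the acceptance checks use 201² oracle
grids, three viscosity ratios (2, 5, 10), three flow rates spanning the
aggregation-relevant shear range, and a 200-frame recording.  These sizes
were chosen so that each check is statistically meaningful for the
property it tests while the whole suite stays interactive; every
simulation is seeded and bit-reproducible on one platform.

# Known limitations

* The interface estimate comes from the tracer-density edge at half
  maximum; a systematically biased edge (for example strongly asymmetric
  tracer bleed across the interface) would propagate into the viscosity.
  A configuration override accepts an externally measured interface
  position.
* The co-flow model assumes a flat vertical interface; strongly curved
  interfaces (large viscosity contrasts combined with low interfacial
  tension) are outside the model.
* Yield-stress constitutive laws (Casson, Herschel–Bulkley) and
  time-dependent (thixotropic) behavior are out of scope.
* Hematocrit and temperature are metadata labels, not model inputs: the
  package fits whatever curve it is given and does not predict hematocrit
  dependence.
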