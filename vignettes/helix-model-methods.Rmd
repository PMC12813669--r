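---
title: "The concentric circular-helix model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The concentric circular-helix model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrehelix)
```

## The scientific problem

Fast axial muscle fibres in larval fish wind around the body in nested
helices: near a transverse "helix centre" fibres run longitudinally, and the
angle to the body axis grows with distance from that centre. `fibrehelix`
quantifies this architecture from segmented 3D fibre data: it fits a
geometric model of concentric circular helices to the measured fibre
orientation angles of one fish, produces confidence bands for the helix
centre and pitch along the body, and compares pitch across a cohort of fish
of different sizes.

## The straightened coordinate system

All positions and orientations are expressed relative to the notochord. A
smooth centreline is fitted through ordered annotation points — a natural
cubic interpolating spline per coordinate against cumulative chord length,
optionally a smoothing spline (`smoothing` maps to `smooth.spline`'s `spar`;
the default 0 interpolates, which keeps the residual to the annotations
below a voxel and recovers the arc length of curved test geometries to well
under 1%). The curve is resampled at uniform arc-length steps (512 by
default, with a dense 50-per-annotation-point intermediate grid for the
arc-length reparameterization).

Transverse frames are transported along the centreline with the
double-reflection rotation-minimizing-frame method. This realizes the
correction for embedding misalignment, body curvature and torsion without
introducing spurious twist: on planar curves the transported dorsal
direction provably does not rotate about the tangent, which the test suite
verifies, and on curves with torsion the transport converges with step size
(checked against a 10x-resolution transport of the same curve). Frames are
anchored by a user-supplied dorsal hint at the anterior end.

`straighten()` projects each point orthogonally onto the smooth curve
(golden-section refinement around the nearest resampled point); `x` is the
arc length of the foot, `(y, z)` the offsets along the local dorsal and
lateral directions after removal of any residual tangential component, so
the transverse radial distance is preserved exactly. Points whose nearest
foot is ambiguous (a second near-minimal distance more than 5% of the body
length away in arc length, as can happen in strongly recurved anterior
anatomy) are flagged and excluded downstream rather than silently assigned.

Longitudinal positions are normalized so the anterior-most fluorescent
muscle is `x = 0` and the posterior-most `x = 1`; transverse coordinates
are divided by the same span, so the whole geometry is in normalized
body-length units and comparable across fish. Angles are reported in
degrees throughout; internal trigonometry is in radians.

Fibre records with `|α|`, `|β|` or `θ` strictly greater than 45° are
removed as segmentation outliers. The rule is applied to magnitudes —
`α` and `β` are signed, and a one-sided rule would discard only one
chirality — and the boundary value 45.000° is kept (strict inequality).

Fibres are assigned to the epaxial (dorsal) or hypaxial (ventral)
compartment by the sign of `y` relative to the horizontal septum, taken at
`y = 0` (the notochord centre) with a configurable offset. Left-side
records are mirrored to the right (`z`, `v_z`, `α` change sign) under the
bilateral-symmetry assumption before fitting.

## The helix model

For a fibre at `(y, z)` and normalized position `x`, with helix centre
`(y_c(x), z_c(x))` and slope `c(x)`:

* `tan α_m = −c(x) · (y − y_c(x))`
* `tan ϕ_m = c(x) · (z − z_c(x))`

These are exactly the projection angles of the tangent of a circular helix
of pitch `ℓ_p = 2π / |c|` (in body lengths per turn) whose pitch does not
vary with the radial distance `R` — equivalently `tan θ_m = |c| · R`, so
the pitch angle grows with distance from the centre while the pitch itself
is constant across radii. The package validates this equivalence against
finite-difference tangents of parametric helices over a broad sweep of
radii, pitches and phases (the `angle_oracle_sweep()` study). The sign of
`c` encodes chirality; with the sign convention above, epaxial fields fit
`c > 0` and their mirror images across the horizontal septum fit `c < 0`.
The convention was fixed so that, epaxially, the largest positive frontal
projection angles sit near the horizontal septum and the most negative ones
dorsally, with sagittal angles maximal laterally — the pattern observed in
larval zebrafish.

The centre coordinates vary along the body as 4th-order polynomials of
`x` and the slope as a 3rd-order polynomial (5 + 5 + 4 = 14 coefficients).
`fit_helix()` minimizes the summed squared angular residual
`Σ (α_i − α_m,i)² + (ϕ_i − ϕ_m,i)²`, computed on angles in degrees (not
their tangents), per compartment, over the full fibre set of one fish.

### Numerical choices

* **Optimizer**: Levenberg–Marquardt (`minpack.lm::nls.lm`) with an
  analytic Jacobian; cost tolerance `1e-10`, at most 10,000 function
  evaluations. Noise-free synthetic fields are recovered to well below the
  optimizer tolerance scale.
* **Initialization**: centre polynomial constants start at the compartment
  fibre centroid with higher-order terms 0; the slope constant starts at
  the sign-aware least-squares slope of `tan α` against `−(y − ŷ_c)`
  pooled over the middle third of the body, where the helix is best
  defined. A user-supplied `init` overrides this.
* **Covariance**: the Gauss–Newton approximation `σ² (JᵀJ)⁻¹` at the
  optimum, with `σ²` the residual mean square. If the design is rank
  deficient — an all-longitudinal field makes the centre unidentifiable —
  the Moore–Penrose pseudo-inverse is used and the fit is flagged
  `ill_defined`.
* **Confidence bands** (`evaluate_fit()`): `var(y_c(x)) = m(x)ᵀ Cov m(x)`
  with `m(x)` the monomial vector (likewise `z_c`, `c`), and a first-order
  delta method through `ℓ_p = 2π/|c|`, so `se(ℓ_p) = 2π · se(c) / c²`.
  Where `|c(x)|` is not distinguishable from zero at the requested level
  (or `|c| < 1e-8`), the pitch CI is marked unbounded rather than reported;
  `standardized_pitch()` excludes such locations. This reproduces the
  expected degeneracy in the tail, where fibres run nearly longitudinally.
* **Degenerate inputs**: fewer fibres than coefficients, `x_norm` outside
  `[0, 1]`, or a zero normalization span are rejected with errors; a zero
  slope yields an infinite pitch sentinel with a warning.

## Residual diagnostics

Residuals `Δα`, `Δϕ` are computed per fibre at its own position and indexed
by the direction `ζ` around the fitted centre at the fibre's `x`
(`ζ = 0` dorsal, `ζ = 90°` lateral; fibres at the centre itself have no
direction and are excluded from direction-indexed curves but kept in scalar
summaries). The circular moving average uses a 90° full window, inclusive
endpoints, queried on a 1° grid, with wrap-around; it commutes with
constants and attenuates a pure sinusoid by `sin(w/2)/(w/2)` (0.9003 at
90°), which the tests verify on a dense grid. An elliptical rather than
circular helix cross-section appears as a two-lobed sagittal residual
pattern — a positive lobe along the stretched axis and an opposite-sign
lobe in the opposite quadrant — whose amplitude grows with the axis ratio.

Per-fish mean absolute residuals are summarized with a normal-approximation
CI (`mean ± 1.96 · SD/√n` across fibres). How such CIs were constructed for
the published figures is not derivable from the data alone; the
across-fibre normal approximation is the simplest defensible choice and is
flagged unavailable for groups of fewer than two fibres.

## Cohort statistics

Pitch is extracted at standardized locations (30, 40, 50, 60, 70% of the
body) with `SE = (CI_hi − CI_lo) / (2 · 1.96)` and modelled as

```
pitch ~ axial_muscle_length + location,  random intercept per fish
```

with inverse-variance observation weights. Location is categorical with
30% as reference, so the reported coefficients are contrasts against the
anterior location (a continuous-location variant is available via
`location_continuous = TRUE`). Epaxial and hypaxial compartments are fitted
separately. Degrees of freedom and p-values come from `nlme`'s containment
method.

One weighting decision deserves emphasis. By default the pitch standard
errors are treated as *known* measurement SDs (the residual scale is fixed
at 1, `nlme::lmeControl(sigma = 1)`) — the standard meta-analytic use of
inverse-variance weights. The alternative, estimating a free residual
scale with the SEs acting only as relative weights, is anticonservative
here: pitch errors at nearby locations from the same fit are strongly
positively correlated (they share the fitted slope polynomial), the random
intercept absorbs much of that shared error, and the estimated scale
shrinks — deflating the fixed-effect standard errors. The package's
calibration study (`cohort_recovery_study()`, run at full size by the
acceptance script) shows the known-SE variant achieves near-nominal
coverage of the location contrast while the free-scale variant does not.
The free-scale variant remains available via `known_se = FALSE`.

## The synthetic-data generator

`generate_field()` inverts the helix model: fibre positions are sampled
area-uniformly in an annulus around the (polynomial) centre — by default
0.02–0.12 normalized units, centres near `y_c = ±0.1`, `c = ±8π` (pitch
0.25, four turns over the body), matching the scale of measured larval
fields — true angles follow the model under the shared sign convention,
and independent Gaussian noise (default SD 3°) is added to `α` and `ϕ`.
Gaussian angular noise is an assumption, chosen so that CI calibration is
testable; the measured residual distributions motivate the scale but not
the shape. Ellipticity stretches the recorded displacement (axis ratio
`≥ 1` at a configurable orientation) while angles keep the circular
geometry, reproducing the direction-structured sagittal residuals of real
data. A single seed makes every field reproducible; cohort generation fans
one seed out into independent per-fish streams.

`generate_cohort()` (defaults: 18 fish, axial muscle lengths uniform on
2.3–3.1 mm mapped onto ages 2–13 dpf, 542 fibres per fish — the cohort
average yield, per-fish random intercept SD 0.05) builds each fish's true
pitch profile as a linear function of `x` (`0.25 + 1.25 x` plus length
effect and fish intercept, i.e. a +0.5 pitch contrast between the 30% and
70% locations and an anterior pitch of about a quarter body length), and
converts it to a cubic slope polynomial by exact interpolation at four
nodes spanning 30–70% — so the contrast between the reference locations is
realized exactly and the cubic extrapolates smoothly over the whole body.
The truth table records both design and realized pitch.

`render_stack()` renders fibres as finite cylinders with per-fibre random
plateau intensities (emulating the random expression-level variation that
makes neighbouring fibres separable), Gaussian blur and noise, and returns
a ground-truth label volume; overlapping cylinders are resolved to the
brighter fibre and flagged.

What the generator does **not** emulate: a realistic point-spread function,
bleaching or depth attenuation, myoseptal geometry and fibre curvature,
cross-sections that change shape along a fibre, or segmentation-induced
shape errors. Passing tests on synthetic data therefore demonstrate the
correctness and calibration of the estimation machinery under the model's
own assumptions (plus angular noise and elliptical distortion), not the
fidelity of any particular microscope or segmentation pipeline on real
tissue.

## Segmentation

The image chain is: 3×3×3 median despeckling, background subtraction (the
20% intensity quantile), anisotropy-aware separable Gaussian smoothing
(sigma in µm, converted per axis by the voxel spacing), rescaling to
[0, 1]; then seeded watershed and size filtering; then per-segment moments.

Seeds are the connected components of the superlevel set
`{intensity ≥ seed_threshold}` — the plateaus containing the local maxima.
Strict voxelwise maxima were rejected as seeds because under noise a single
fibre carries many of them, fragmenting tubes. Segments grow from the seeds
by priority-flood watershed over the foreground mask
`{intensity ≥ fg_threshold}`, always expanding through the brightest
unassigned voxel (FIFO tie-break), so boundaries between touching fibres
fall along their intensity valleys; labels partition the foreground. All
thresholds are configuration entries; the defaults (seed 0.4–0.5, fg
0.15–0.2 relative, size bounds 60–3000 voxels at ~2 µm³ voxels) were
calibrated on the rendered synthetic fixture only.

Principal axes are computed from the *unweighted* voxel coordinate cloud in
physical units (spacing-corrected): intensity weighting would couple the
deliberate brightness variation between fibres into the geometry. The
elongation (square root of the ratio of the largest to middle eigenvalue)
flags non-fibre segments (`< 2`), replacing manual curation, which is out
of scope.

## Problem sizes used in the validation studies

The packaged studies run at: 1000-point oracle sweep; 100 replicates of
800-fibre fields at 3° noise for parameter recovery and CI coverage; 100
replicate pairs of 200-fibre mirrored fields for chirality; 2000-fibre
fields for ellipticity detection at axis ratios 1–1.3; 100 replicates of
18-fish cohorts (542 fibres per fish) for pitch-trend recovery; and a
20-fibre rendered stack (96×72×48 voxels at 1×1×2 µm) for the segmentation
benchmark. These sizes reflect the study conditions being emulated (the
cohort matches the 18-fish, ~9751-fibre design) and give the Monte-Carlo
statements a resolution of one percentage point.

## Known limitations

* The model assumes circular cross-sections and a pitch independent of the
  radial distance; elliptical and radius-dependent-pitch variants are
  deliberately out of scope (the residual diagnostics are designed to
  *detect* ellipticity, not fit it), as is model selection across such
  variants.
* Anteriorly (head attachment, pectoral girdle) and posteriorly
  (near-longitudinal fibres) the parameters are weakly constrained; the
  machinery reports this honestly (wide or unbounded CIs, `ill_defined`
  flags) rather than extrapolating.
* The coordinate system is anatomical (notochord-relative), not a swimming
  reference frame; no body-undulation kinematics are modelled.
* The longitudinal helix-centre coordinate appears in the symbol
  inventory of this model family but no equation here uses it; only the
  transverse centre `(y_c, z_c)` is estimated.
* `x_norm` spans the fluorescent muscle extent of each fish, so positions
  are comparable across fish only under the isometric-growth assumption.
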