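---
title: "Modelling laser dazzle: veiling glare, a retina-like sensor, and grey-AHP grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling laser dazzle: veiling glare, a retina-like sensor, and grey-AHP grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dazzlesim)
```

# The problem

A visible laser aimed near an observer's line of sight scatters inside the
eye and superimposes a *veiling luminance* on the retinal image. The veil
does not damage the retina at the exposures considered here; it degrades
visual performance by washing out contrast, so a target that was easily
visible may become undetectable within some angular region around the
source — *disability glare*, colloquially dazzle. `dazzlesim` packages a
quantitative model of this effect together with two companion components: a
simulator for a foveated, logarithmically-responding image sensor of the
kind used to record dazzle imagery in hardware, and a grey analytic
hierarchy process (G-AHP) that converts scenario measurements into a
four-level interference grade.

# The glare model

## Veiling luminance

The angular kernel is the CIE general disability-glare equation,

$$g(\theta, A, p) = \frac{10}{\theta^3}
  + \left[\frac{5}{\theta^2} + \frac{0.1\,p}{\theta}\right]
    \left[1 + \left(\frac{A}{62.5}\right)^4\right] + 0.0025\,p,$$

with $\theta$ the glare angle in **degrees** (the CIE convention used
throughout — angles are never radians in the user API), $A$ the observer
age in years and $p$ the iris pigmentation coefficient (0 very dark eyes to
1.2 very light). The veil produced by an eye-plane irradiance $E_e$
(mW/cm²) against background luminance $L_b$ (cd/m²) is

$$L_v = S_1\,L_b^{T_1}\, g(\theta, A, p)\; \cdot\; 683\,V(\lambda)\,E_e',$$

where $E_e'$ is $E_e$ converted to W/m², $V(\lambda)$ is the CIE photopic
efficiency (tabulated 380–780 nm at 5 nm, linearly interpolated) and
$S_1 = 0.9147$, $T_1 = 0.1775$ calibrate the dependence on the adaptation
background. The photometric factor $683\,V(\lambda)E_e'$ is the *visual
corneal illuminance*: the kernel relates veil luminance to illuminance at
the cornea, so a radiometric exposure must pass through $V(\lambda)$ before
entering the model; this is also what makes the output dimensionally a
luminance. `veiling_luminance()` is exactly linear in $E_e$, which the test
suite checks as an identity rather than numerically.

## Threshold contrast and the masking criterion

Whether the veil *matters* depends on the observer's contrast threshold.
We use the classical small-target visibility form

$$C_{thr}(L_b, a, A) = \frac{2.6}{L_b}
  \left(\frac{\sqrt{\Phi}(L_b)}{60\,a} + \sqrt{L}(L_b)\right)^2 \, AF(A),$$

with $a$ the target subtense in degrees ($60a$ converts to arcminutes) and
$AF$ a two-branch quadratic age factor ($AF(19) = 0.99$; branch change at
age 64, clamping with a warning outside 19–75). The luminance functions
$\sqrt{\Phi}$ and $\sqrt{L}$ are the Adrian (1989) visibility calibration,
defined piecewise over three adaptation regimes with branch joins at
0.00418 and 0.6 cd/m²; the suite verifies the branches meet within 2%.
They are deliberately *pluggable* through `glare_calibration()`: any
alternative calibration of the same shape can be swapped in without
touching the rest of the model. This is the model's single largest source
of absolute uncertainty, discussed under *Limitations*.

A target of intrinsic contrast $C_{orig}$ under veil $L_v$ has effective
contrast

$$C_w = C_{orig}\,\frac{L_b}{L_b + L_v},$$

the standard veiling-glare contrast reduction. The target is *masked* at
angle $\theta$ when $C_w(\theta) < C_{thr}$. We evaluate $C_{thr}$ at the
ambient adaptation $L_b$ (not $L_b + L_v$): for brief exposures the eye
remains adapted to the pre-exposure field, and this choice keeps the
masking criterion monotone in $\theta$, guaranteeing a unique dazzle
boundary.

## Derived quantities

* `dazzle_angle()` — the largest masked angle $U$, by bisection on
  $[0.01°, 90°]$ to $10^{-4}$ degrees. The veil decreases strictly with
  angle, so the masked set is an interval and bisection cannot miss the
  boundary. Zero irradiance short-circuits to $U = 0$; if even 90° is
  masked the upper bound is returned with a warning.
* `mde()` — maximum dazzle exposure, the closed-form inverse: the
  irradiance making $C_w = C_{thr}$ exactly at a given angle. A scene whose
  unlit target is already below threshold is rejected as degenerate.
  `mde()` and `dazzle_angle()` are verified as mutual inverses to $10^{-3}$
  relative over a grid of angles, luminances, ages, pigmentations and
  contrasts.
* `mpe_visible_cw()` — the visible-band continuous-wave maximum permissible
  exposure under the aversion-response assumption, $18\,t^{0.75}/t$ W/m²
  for $0 < t \le 10$ s (≈25.5 W/m² at the 0.25 s blink reflex). Pulsed
  regimes, retinal thermal limits and extended sources are out of scope by
  design; the function refuses them rather than extrapolating.
* `eye_irradiance_at_distance()` — far-field circular top-hat beam of
  diameter $d_0 + \varphi L$; `nohd()` and `nodd()` invert it at the MPE
  and at the MDE respectively. The round trip
  irradiance-at-NOHD $=$ MPE holds to $10^{-6}$ relative.
* `safety_gate()` — alarm when irradiance strictly exceeds $w \cdot$MPE,
  $w \in [0.3, 0.8]$ (default 0.5); the boundary itself passes.

# The retina-like sensor

`ring_detector_config()` describes a concentric-ring mosaic: 50 fovea
rings at a constant 14 µm radial pitch surrounded by 88 peripheral rings of
520 pixels each whose radial extents grow geometrically until the disc
radius (5113 µm) is reached exactly — the log-polar compromise that mimics
falling photoreceptor density. The published per-ring fovea pixel counts
are not available, so the default schedule assigns ring $k$ a count
proportional to its circumference, $6306\,(2k-1)/50^2$, corrected by
largest remainder to sum to exactly 6306. With these defaults the layout
reproduces the reference bookkeeping (138 rings, 52,066 pixels) as an
exact integer identity. The size-ratio summaries R and Q are reported as
*emergent* metrics of the built layout; the reference values are carried as
metadata because the pixel-size measure behind the printed R is not
defined, and Q = 2·5113/14 = 730.4 rounds ambiguously.

Pixels respond logarithmically: $r = d + g\,\log(1 + v)$ with input clamp
at saturation, inverted exactly by `log_pixel_decode()` below clamp.
Sampling (`retina_sample()`) averages scene luminance over each pixel
footprint by grid supersampling (default 4× per cell edge) rather than
analytic polar integration — exact for the piecewise-constant scenes used
in testing and accurate to the supersampling resolution otherwise.
Reconstruction paints each output cell with its containing pixel's decoded
value; a constant scene round-trips exactly, and refining the ring count
provably reduces reconstruction error on smooth radial scenes (checked by
a refinement study in the suite).

# The spot pipeline

`process_spot()` chains three stages:

1. **Extraction.** Otsu binarization (parameter-free; a fixed threshold is
   available), Canny edge detection, and first-moment geometry. The radius
   of an irregular spot is defined as the equivalent-area circle radius
   $\sqrt{A/\pi}$. Canny is implemented in full — separable Gaussian
   smoothing, Sobel gradients, non-maximum suppression along the gradient
   direction quantized to the eight compass offsets, and double-threshold
   hysteresis grown to a fixpoint over 8-connectivity — with defaults
   $\sigma = 1.4$, low/high $= 0.1/0.3$ of the maximum gradient magnitude.
2. **Compensation.** Real spot images arrive with defects (notches,
   occlusions, dropouts). The spot *domain* is taken as the convex hull of
   the foreground, the largest inscribed ellipse of that domain is found
   (distance-transform seed, coordinate-ascent refinement of centre, axes
   and rotation; a local area maximum, not a certified global optimum),
   and a gamma transform ($s = c\,r^\gamma$, default $\gamma = 0.8$)
   enhances contrast. The Gaussian profile is then fitted by
   Levenberg–Marquardt least squares **to the observed foreground cells
   only**, and the fitted model completes the compensation by imputing the
   replenished cells. Fitting before imputing is deliberate: imputed values
   carry no information, and letting them into the objective would bias
   the centre toward whatever heuristic filled them.
3. **Halo overlay.** `halo_profile()` samples the veiling luminance over
   image radii (degrees per cell supplied by the caller) and
   `overlay_halo()` composites it onto the spot in linear intensity
   (additive by default, screen as an alternative), then min–max
   tone-maps to the display range. Linear-domain energy additivity is
   checked exactly in the suite.

The synthetic generator `generate_synthetic_spot()` produces elliptical
Gaussian spots with a circular-bite defect and seeded additive Gaussian
noise. Its defaults (64×64 cells, $\sigma \approx 7$ cells, 1–2% noise,
notch radius ≈ $0.7\sigma$) emulate the defect severity visible in real
spot imagery. What it does **not** emulate: speckle phase noise, detector
fixed-pattern noise, saturation bloom, and non-Gaussian beam profiles — so
a passing recovery test demonstrates correctness of the pipeline on its
stated model class, not performance on arbitrary hardware images. Over 20
seeded defected spots the suite requires median centre error < 0.5 cells
and median compensated-radius error < 5% against generator truth.

# Grey-AHP grading

The hierarchy has four criteria — incident laser radiation characteristics
(U-A), retinal physiological damage (U-B), retinal imaging characteristics
(U-C) and laser glare perception (U-D) — with 5/2/3/5 indicators carrying
3,3,2,2,3 / 3,2 / 3,2,2 / 2,2,2,2,1 leaf factors. Weights at every node
come from pairwise judgment matrices via the geometric-mean method, with
the consistency ratio reported and a warning above the 0.1 admissibility
bound; on near-consistent matrices the weights agree with the
principal-eigenvector method to well under 2%, which the suite checks
against a power-iteration oracle. The original expert matrices are not
published, so the shipped default is the neutral all-ones matrix (equal
weights) at every node, and consequently the shipped per-scene reference
levels are a regression fixture, **not** a reproduction target.

Criterion scores map to the four grey classes through trapezoidal
whitening functions over the class intervals
(U-A: 0–2–4–5–6, U-B: 0–3–5–6–9, U-C/U-D: 0–2–3–4–5): full membership on
interval interiors, a linear crossfade over a band of 10% of the narrower
neighbouring interval centred on each boundary, memberships normalized to
sum to one, and an exact boundary splitting 50/50. Scores above the top
interval clamp to Extremely High with a warning. The combined class maxes
the weighted memberships, with ties broken toward the more severe class —
the conservative choice for a safety grading — and maps Low→I through
Extremely High→IV.

Because no factor scoring rubric is published either,
`default_leaf_scores()` documents an explicit piecewise-linear rubric:
irradiance is scored against the MPE (reaching the High boundary at the
MPE), spot diameter against the fovea diameter, and occlusion angle
against the target subtense, each saturating at the top of its criterion
scale. All three transforms are configurable.

# The scenario runner

`scenes_s1_s21()` encodes the 21-scene reference grid (two target
contrasts, seven ambient luminances spanning 0.005–491.52 cd/m², incidence
angles 0.5–12°, ages 30–60) with measured eye irradiances attached as
overrides — irradiances in such studies are measured at the pupil, and not
every scene distance is published, so the runner prefers a measured value
and falls back to the divergence model when given a distance instead.
"Detector fully covered" is representable as a saturation flag (`NA`
diameter) that scores at the top of the imaging scale. `run_batch()` is
deterministic given its seed and records per-scene failures in an error
column instead of aborting the batch. `dose_effect_curve()` sweeps ambient
luminance (60-point log grid over 0.001–500 cd/m² by default) or glare
angle and locates crossings of $U$ with the target subtense — or of MDE
with the scene irradiance — by a grid bracket refined with bisection.

# Numerical choices, degenerate inputs

* Bisection tolerances: $10^{-4}$ degrees for the dazzle angle, $10^{-6}$
  (in the swept coordinate) for curve crossings.
* Constant images binarize to an empty mask with a warning; empty
  foregrounds are errors for geometry, as are regions thinner than two
  cells for ellipse inscription.
* The Gaussian fit initializes from intensity moments; a perfect (zero
  residual) fit is handled without error, and non-convergence aborts with
  the moment initialization in the message.
* Angular tiling of each detector ring is exact by construction
  ($2\pi/n$ wedges); the $2\pi$ wrap is guarded when locating pixels.
* Report serialization fixes float formatting (`%.6g`), key order and line
  endings so identical inputs give byte-identical files.

# Problem sizes

The test suite runs on deliberately desk-scale instances: 64×64 spot
images, a 14-ring miniature detector for sampling tests (the full 138-ring
layout is built and audited, but only sampled at reduced scale), 20-seed
recovery sweeps, and 40–80-point dose-effect grids. These sizes keep the
full suite under a minute while exercising every code path; all are
parameters, and nothing in the implementation assumes them.

# Limitations

* **Absolute dazzle calibration.** The veil kernel and the visibility
  calibration come from population-average laboratory data. Dose-effect
  operating points (e.g. the ambient luminance at which dazzle just covers
  a given target) are extremely sensitive to the threshold-contrast
  calibration $\sqrt{\Phi}, \sqrt{L}$ and to how a fielded instrument's
  image chain maps veil luminance to recorded pixels. Instrument-measured
  dose-effect curves can therefore sit orders of magnitude away from the
  analytic crossings computed here; within-model trends (monotonicity in
  irradiance, ambient luminance and angle; the inverse relationship
  between MDE and dazzle angle) are the robust outputs, and those are what
  the suite asserts. Users with access to measured curves should refit the
  calibration functions via `glare_calibration()`.
* Photopic efficiency only: no scotopic or mesopic weighting, although the
  low end of the ambient range is mesopic in reality.
* The inscribed-ellipse search is a local optimizer; pathological
  non-convex masks can yield conservative ellipses.
* The grading defaults (equal weights, documented rubric) are neutral
  placeholders for expert elicitation, not a validated clinical scale.
* No transistor-level sensor simulation: the log-pixel model is an ideal
  monotone response with saturation, without noise spectra or readout
  artefacts.
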