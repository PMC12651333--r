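---
title: "Semi-quantitative lateral-flow strip reading: models and methods"
author: "LFAreader"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-quantitative lateral-flow strip reading: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LFAreader)
```

# The measurement problem

A lateral-flow immunoassay (LFIA) cassette for 25-hydroxyvitamin D
develops a red gold-nanoparticle band at the test (T) line whose optical
density grows with analyte concentration, and a control (C) line that
confirms the strip ran. A phone photograph of the cassette is the raw
measurement. Between the dye on the membrane and the pixels in the file
sit the camera's white balance, lens shading, channel cross-talk,
exposure and sRGB encoding — all of which differ between devices and
scenes. The reader's job is to recover a device- and
illumination-independent estimate of the analyte concentration, and to
report it on a three-level clinical scale: deficient (< 20 ng/mL),
insufficient (20–30 ng/mL, both ends included), sufficient (> 30 ng/mL).

The package implements the full chain: strip detection and perspective
rectification, line-signal extraction, per-image calibration against a
printed reference ladder, concentration regression and classification,
a learned cross-device photometric alignment, and the
analytical-validation statistics used to qualify such a reader (EP17
detection limits, percent agreement with Wilson intervals, Cohen's
kappa, Pearson correlation, Welch intervals). Because no raw strip
photographs are publicly deposited for this assay class, the package
also ships a first-class synthetic generator whose ground truth makes
every stage testable.

# The signal model

## Absorbance on the green channel

All measurement happens in linear intensity (sRGB decoding occurs at
rectification). The longitudinal profile is, per column,

$$ A(x) = -\log_{10}\!\big(\max(\epsilon,\, \bar g(x))\big), $$

where $\bar g(x)$ is the 20% trimmed mean of the green channel over the
transverse central 60% of the strip and $\epsilon = 10^{-4}$. The green
channel is the one a red band absorbs most, and log-transmittance makes
the measure approximately linear in the amount of dye. The trimmed mean
rejects dust and glare specks. Line intensity is the mean of $A$ over
the line window minus the median of two flanking background windows,
clamped at zero. Because a global illumination gain adds a constant to
$A$, background subtraction removes it exactly — this is the mechanism
behind the illumination-invariance property the tests verify.

Peak localisation inside each expected window is the profile maximum
with ties broken toward the window center. For measurement the package
first applies a line-width moving average (a matched filter for a
rectangular band): on a noisy plateau the raw argmax wanders to the
plateau edge and drags the measurement window off the line, while the
matched filter's maximum sits at the plateau center. The measurement
itself always uses the unsmoothed profile.

## The printed reference ladder

Five reference lines of known nominal signal $R_k$ (defaults 10, 20,
40, 60, 80 signal units) are printed on the strip. Each analyzed image
is calibrated against itself: ordinary least squares of $R_k$ on the
measured intensities $I_k$ gives

$$ S = g(I) = a_0 + a_1 I \;(+\, a_2 I^2), $$

linear by default with a quadratic option. Points whose absolute
residual from a provisional line exceeds three times the median
absolute residual are masked (at least two must survive), and a fitted
curve that is not strictly increasing over the ladder's intensity range
is rejected — an inverted ladder means the image cannot be trusted.
This per-image mapping is what makes readings comparable across devices
and exposures: any effect that rescales intensities consistently is
absorbed by $g$.

## Concentration and classification

Standardized signals $S_T = g(I_T)$, $S_C = g(I_C)$ and the
control-normalized ratio $S_{T|C} = S_T / S_C$ feed a linear regression

$$ \widehat{c} = \alpha' \, S_{T|C} + \beta', $$

fitted once per kit lot from a reference panel (the `"ST"` mode uses
$S_T$ directly; the control-normalized mode is the default because the
C line tracks residual run-to-run effects). Estimates outside the 5–100
ng/mL reportable range are censored as `"<5"` or `">100"` — carried as
markers, never silently clamped — and the in-range estimate is binned
at 20 and 30 ng/mL with the middle class closed on both ends.

# The synthetic generator

`renderStrip()` draws the canonical strip (600 x 120 px; C line at 0.15
of the length, T at 0.30, reference lines at 0.50–0.90) in linear
reflectance: substrate 0.75, per-line transmittance
$10^{-w_{ch} d}$ with channel weights $w = (0.1, 1.0, 0.8)$ for
R, G, B — a red band. Line edges ramp over ~2 px, as dye diffuses at a
band boundary. The strip is then homography-warped onto a darker canvas
(background 0.25) and passed through a device model in a fixed order:
multiplicative shading field, 3x3 channel mixing, intensity scale,
inverse white-balance tint, optional sRGB encoding, additive Gaussian
noise (default sd 0.004, about one 8-bit count), clipped to [0, 1].
Identical inputs and seed give identical pixels.

Choices a reader of the tests should know about:

* **Dose–response.** The T-line density follows a Langmuir form
  $d(c) = d_0 + d_{max} c / (k_{1/2} + c)$ with defaults
  $d_{max} = 1$, $k_{1/2} = 250$ ng/mL, $d_0 = 0.02$. The
  half-saturation constant is anchored to the observed behaviour of
  readers of this class: a linear readout over 5–100 ng/mL must track a
  laboratory reference with $R^2 \approx 0.99$, which requires only
  mild curvature inside the measuring range ($k_{1/2} = 250$ gives a
  panel-fit $R^2$ of 0.992), with the binding plateau well beyond it.
  A strongly saturating curve (say $k_{1/2} = 50$) would contradict
  that linearity and misclassify mid-range samples under any linear
  concentration model.
* **Substrate at 0.75, not 1.0.** A white membrane photographed at
  sensible exposure does not sit at clipping; this keeps illumination
  gains up to x1.3 in gamut so the invariance property is about the
  algorithm, not about saturation artifacts.
* **Capture resolution.** Default poses render the strip at or slightly
  above canonical resolution (`makePose(scale = 1.05)`), as guided
  capture in a reader app enforces. Rectification from a photo that
  *under*-resolves the strip necessarily blurs line edges and degrades
  the round-trip fidelity checks.
* **Signal-to-density map.** The true optical mapping of printed
  reference inks is not public; the generator uses a linear stand-in
  (density = 0.01 R_k). All calibration logic is agnostic to this
  choice.

What the generator does **not** emulate: membrane texture, flow
dynamics and drying artifacts, hook effects at extreme concentrations,
specular glare geometry, lens distortion, JPEG compression, and
chemistry-level variability (lot, operator, pipetting). Passing tests
therefore demonstrate the correctness and internal consistency of the
computational pipeline under a faithful optical model — not the wet-lab
performance of any physical kit.

# Geometry

Detection is classical: luminance gradient magnitude, Otsu threshold
(with an absolute contrast floor of 0.05 so a featureless image fails
cleanly), convex hull of the edge pixels, merging of near-collinear
hull segments, the four longest segments as the strip sides, and
corners from intersecting adjacent total-least-squares side fits (two
refinement passes). On synthetic poses within ±25° rotation and
moderate perspective the corners come back well under a pixel of truth.
Rectification is a 4-point DLT homography with bilinear resampling; the
strip boundary maps to pixel *edges* of the canonical frame, so every
canonical pixel center lies strictly inside the physical strip.
Coordinates throughout are 1-based (row, col) with the origin at the
top-left, the R convention; corner quadrilaterals are ordered clockwise
from the top-left.

QC flags: overexposure when more than 5% of rectified pixels reach 0.99
in any channel (configurable), and insufficient reaction when the
control line's background-corrected absorbance falls below 0.05. An
insufficient-reaction flag short-circuits the pipeline: the record
carries flags and no concentration.

# Cross-device alignment

One device is designated the reference; captures from another are
mapped into its linear space by four sequentially fitted steps:
(i) sRGB linearization; (ii) white-balance gains
$(\bar m / m_R, \bar m / m_G, \bar m / m_B)$ from channel medians over
the cassette's neutral zone; (iii) division by a degree-2 polynomial
shading field fitted to background luminance; (iv) a 3x3 color
correction matrix with a separate intensity scale,
$\min_M \sum_i \| s M x_i - y_i \|^2$, fitted on paired patch means
(the five reference-line windows, the C line, and the neutral zone).
The scale $s$ is the target/source mean-luminance ratio, so $M$ is
luminance-neutral — a convention, reported alongside $M$. Sequential
fitting keeps every sub-problem linear; the shading field commutes with
the per-pixel matrix, so the order is consistent with a device whose
distortions were applied in the generator's order.

Two kinds of checks deliberately run at different noise levels. The
pixel-level fidelity check (held-out aligned pair RMS < 0.01) runs at
noise sd 0.001: sRGB decoding has slope ≈ 2 near white, so at the
default sd 0.004 the shot noise of two captures alone contributes
≈ 0.011 RMS to their difference and would mask any alignment residual.
The category-agreement checks run at the full default noise — the
claim that matters clinically.

The 12-member concordance panel spans 5–100 ng/mL with every category
represented, and its members are placed so their *expected readings*
sit well clear of the 20/30 cutoffs, with replicate members at the
center of the insufficient band. A specimen whose expected reading lies
at a cutoff has an undefined expected category: two perfect readers
split on it with probability one half, so 100% agreement can only be a
property of an off-cutoff panel — the standard design consideration for
qualitative-agreement studies.

# Validation statistics

* **Detection limits** (EP17): $LoB = \bar x_{blank} + 1.645\,SD_{blank}$
  and $LoD = LoB + 1.645\,SD_{low}$, sample SDs with $n-1$. From the
  published summary inputs (blank mean 0.5, SD 0.2, low-level SD 2.5)
  these evaluate to 0.829 and 4.9415 ng/mL; the package reports the
  formula values (the source report rounds the latter to 5.0).
* **Wilson score intervals** with $z = 1.959964$ and no continuity
  correction; this reproduces the printed one-decimal CI bounds for
  14/15, 6/7, 3/3, 12/12 and 45/46. `stats::prop.test(correct = FALSE)`
  serves as the independent oracle in the tests.
* **Cohen's kappa**, unweighted by default — the printed headline value
  0.951 for the bundled serum table is the unweighted statistic — with
  linear and quadratic weights available
  ($w_{ij} = 1 - (|i-j|/(K-1))^q$). Perfect agreement returns 1 even
  when concentrated in a single category (the 0/0 guard).
* **Welch intervals** and **Pearson r** delegate to `stats`.

The synthetic detection-limit study (`lodStudy()`) runs the full
imaging pipeline on replicate blank and low-level strips and applies
the EP17 formulas to the uncensored estimates. Under the default
generator and a linear 5–100 calibration, blanks extrapolate to about
−5 ng/mL (the line is anchored to the range, not the origin) with a
per-replicate spread of ≈ 2 ng/mL, so the synthetic system's LoD lands
near zero — below the reportable floor. Recovery is therefore assessed
as agreement between a 20-replicate study and a high-replicate
reference run, scaled by the larger of the reference limit and the
5 ng/mL range floor: two studies agreeing within 20% of the floor agree
on the claim that matters, "LoD < 5".

# Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic
data: canonical frames are 600 x 120 px and posed photographs about
400 x 900 px; calibration panels use 8 levels x 3 replicates;
detection-limit studies 20 (study) and 60 (reference) replicates per
level; concordance panels 12 strips. Tolerances: exact algebraic
recoveries are asserted at 1e-6–1e-9; image round-trips at the
resampling scale (1e-3 for the identity warp, correlation > 0.99 for
full round trips); statistics against printed values at the printed
precision. Ties in peak location break toward the window center;
degenerate inputs (collinear corners, flat ladders, rank-deficient
designs, dark neutral zones) raise errors with stage-tagged messages
rather than propagating nonsense.

# Limitations

The reader is only as good as its layout prior: detection assumes one
high-contrast rectangular strip on a darker background, and line
windows come from the configured layout, not from content. The
classifier is semi-quantitative by design; the censoring markers are
not estimates. The photometric transform assumes the source device's
distortions are static per device (no auto-exposure compensation or
RAW-level processing), and the generator's noise model is additive
Gaussian — real sensors are Poisson-dominated at low light. None of the
synthetic results certify wet-lab assay performance.
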