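---
title: "Positional-similarity screening for strabismus: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positional-similarity screening for strabismus: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strabscreen)
```

## The screening problem

Strabismus is a misalignment of the visual axes: when one eye fixates a
target, the other deviates nasally (esotropia), temporally (exotropia), or
vertically. Screening normally requires an ophthalmologist (cover test,
Hirschberg corneal-reflex test) or dedicated devices (photoscreeners, eye
trackers). `strabscreen` targets the opposite setting: a single frontal
photograph taken by a non-specialist, processed by transparent image
operations whose every intermediate product can be audited.

The core idea is geometric. In an aligned pair of eyes the iris sits at
mirror-symmetric positions within the two palpebral fissures, so the ratio of
distances from the pupil center to the lateral and medial canthus is the same
for both eyes. The positional similarity

$$S = \frac{\max(r_R, r_L)}{\min(r_R, r_L)}, \qquad
  r = \frac{d_\text{lateral}}{d_\text{medial}},$$

is 1 for perfectly symmetric placement and grows as one iris deviates. Using
a ratio within each eye makes $S$ invariant to image scale and to the
inter-eye distance; taking max over min makes it invariant to which eye
deviates and bounds it below by 1.

## Pipeline stages and parameter choices

### Coordinates

All coordinates are 1-based pixel positions (x = column, y = row, y
increasing downward), the native R raster convention; rectangles are
inclusive of both corners. Crop-local and source coordinates are related by
`source = local + offset − 1`, and the suite's translation-equivariance and
canthus-reconstruction tests pin this convention down exactly.

### Eye extraction

The right-eye rectangle runs from $(x_{37}-e,\,y_{38}-e)$ to
$(x_{40}+e,\,y_{41}+e)$ in the iBUG 68-point layout; the left eye uses
indices 43/44 and 46/47 by symmetry. The expansion $e$ (default 10 px)
absorbs landmark placement error so the whole fissure is always inside the
crop. Landmarks 37/40 are the right eye's lateral/medial canthi, 43/46 the
left eye's medial/lateral ones. Rectangles are clamped to the image; a crop
that clamps to zero area is an extraction error rather than a silent empty
result.

A face/landmark detector is deliberately not bundled: detection backends are
large pretrained models outside this package's scope. `detect_landmarks()`
defines the pluggable contract (input downscaled by `resize_factor`, default
1/2, to bound detector memory; coordinates rescaled back; exactly one face or
an error) and landmark files are the default ingestion path. All processing
after detection runs at full resolution — downscaling exists only to cheapen
detection, and $S$ is scale-invariant per eye in any case.

### Segmentation

* **Smoothing.** 5×5 separable Gaussian, reflective borders. The kernel width
  is specified but not its shape; we use the standard size-derived sigma
  $\sigma = 0.3((k-1)/2 - 1) + 0.8 = 1.1$ for $k = 5$, configurable.
* **Grayscale.** BT.601 luma ($0.299R + 0.587G + 0.114B$), the common default
  of imaging libraries, rounded half-away-from-zero for determinism.
* **Otsu threshold.** Exhaustive over the 256-bin histogram, maximizing
  $\omega_0\omega_1(\mu_0 - \mu_1)^2$ with class 0 = values $< t$. Three
  conventions the definition leaves open are fixed as: pixels equal to the
  threshold are background (the rule "smaller than → 0" read strictly); ties
  break toward the smallest maximizer; a constant image returns the constant
  (producing an all-background mask) with a warning instead of an arbitrary
  split.
* **HSV dark mask.** 8-bit OpenCV-style dialect ($H \in [0,180]$,
  $S, V \in [0,255]$ — the stated upper hue bound of 180 forces this
  dialect). Bounds default to $[0,0,0]$–$[180,255,v]$ with $v$ = rounded mean
  gray of the *whole* crop: the averaging region is read as the full eye crop
  because the iris is not yet known at this stage. The mask therefore keys
  purely on darkness relative to local illumination.

### Combining the masks

The published per-column rule — find the first dark HSV row, whiten the Otsu
mask from there to the bottom — is implemented verbatim as the `literal`
variant, along with its top/bottom `mirror`. Both have a structural problem:
the HSV dark mask always contains the iris itself (the darkest region is
necessarily below the mean-gray bound), so either scan direction whitens
through the iris in exactly the columns that matter. Which scan orientation
and which mask polarity the original procedure assumed is not recoverable
from its description, while its illustrated output clearly retains the iris.

The default `preserve_central` variant therefore treats orientation as the
open parameter it is: it evaluates both scans and keeps whichever output
retains the larger 8-connected dark component at the crop center — and when
neither retains any central component (the typical case, by the argument
above), it falls back to the unmodified Otsu mask. This respects the
documented invariant that combination never creates foreground
(dark(combined) ⊆ dark(Otsu)), and the fixture-recall requirement that ≥ 90%
of true iris pixels dark in the Otsu mask stay dark. Shadow suppression is
then effectively delegated to the connected-component step, which isolates
the central iris from disjoint shadow blobs; the variants remain selectable
for inspection via `segmentation_config(combine_variant =)`.

### Iris location and circle fit

* **Seed.** The crop center if dark, else the nearest dark pixel on the
  center row (alternating left/right at increasing offsets). A candidate must
  start a horizontal dark run of length ≥ 3 — an unstated but necessary guard
  against isolated noise pixels surviving binarization.
* **Component.** 8-connected (diagonal contact counts); connectivity is
  unstated upstream, and 8-connectivity is the safer choice for anti-aliased
  disc rasterizations whose cardinal neighbours can drop out.
* **Limbus samples.** Per occupied row, bottom-to-top, the leftmost and
  rightmost component pixels. Whether one or both horizontal extrema per row
  are intended is ambiguous ("all of the pixel points located at the
  limbus"); both are used as the faithful superset. Under upper-lid occlusion
  the top rows simply contribute lid-line pixels; an optional `row_fraction`
  restricts fitting to the lowest rows for heavily occluded inputs (default
  1.0: all rows).
* **Fit.** The radius is profiled out: $R$ is tied to the mean sample
  distance at every evaluation, making the objective the variance of the
  distances over $(a, b)$ only. The Kåsa algebraic fit gives the start;
  damped Gauss–Newton refines it to an objective-change tolerance of 1e-9
  (cap 500 iterations, error on non-convergence). Exactly collinear samples
  are rejected as degenerate. On exact-circle samples the Kåsa start is
  already exact, which is why sub-1e-6 px recovery is achievable and tested.

### Classification and statistics

Ratio orientation is fixed as lateral/medial for both eyes; any consistent
convention yields the same $S$, but fixing one keeps per-eye ratios
interpretable. The default cutoff 1.2 sits inside the gap between the ranges
reported for normal (max ≈ 1.14) and strabismic (min ≈ 1.33) eyes in the
validation study this method derives from; it is configurable, and $S$ itself
is always reported — the scalar, not the label, is the screening output.

The one-sided Mann–Whitney test uses the normal approximation with continuity
correction and tie-corrected variance; with two no-tie groups of 30 under
complete separation this gives $U = 900$, $\sigma_U = \sqrt{4575}$ and
$p = 1.51\times10^{-11}$, which the acceptance suite checks to 1% relative.
An exact-distribution mode (`method = "exact"`, no ties, $n_1 n_2 \le 400$)
backs the approximation for small cohorts.

## The synthetic generator: stated world and its limits

`render_eye()` draws a skin field, an almond fissure of sclera between two
canthi, an anti-aliased iris disc with a darker pupil core, an optional
upper-lid occlusion band, oblique eyelash-shadow strokes above the lid, and
clipped additive Gaussian noise. Values chosen once as the generator's stated
world:

* geometry: canthus span = 5 R, lid arcs open to 1.25 R with a
  $\sin^{0.6}$ profile (flat enough that an unoccluded iris is fully visible
  across deviations used in testing); iris radius default 20 px, matching an
  eye crop from a ~2 MP frontal face photograph;
* intensities (8-bit): skin 200, sclera 245, iris 45, pupil 20; shadows
  interpolate between iris and skin by `shadow_strength`;
* cohort rendering: noise σ = 4, occlusion 0.10, shadow strength 0.4 — a
  mildly degraded but usable frontal capture;
* cohorts: normal eyes get ±1 px uniform jitter; strabismic subjects get one
  eye displaced horizontally by a magnitude uniform in 5–15 px (≈ 0.25–0.75 R,
  clinically conspicuous deviations), side and direction random.

The generator emulates what the segmentation stages consume — contrast
between iris, sclera, skin and shadows under varying illumination-like noise.
It does **not** emulate photorealistic texture, corneal light reflexes
(glints), light irides, skin-tone diversity, pose, or landmark-detector
error: landmarks in fixtures are exact, so green end-to-end tests establish
the correctness of the geometry and segmentation pipeline *given* accurate
landmarks, not robustness of any face detector. Real-image performance
additionally depends on the landmark backend's canthus accuracy, which the
original validation identified as its dominant error source.

## Degenerate inputs and numerical notes

* Constant (e.g. all-white) crops: Otsu warns and yields an all-background
  mask; the seed search then raises an iris-not-found error naming the stage.
* Sub-3-sample components are rejected before fitting; single-blob masks with
  < 3 occupied rows cannot anchor a circle.
* All randomness (noise, cohort draws) flows through one seed and a private
  RNG stream, so fixtures are bit-reproducible and the global RNG state is
  untouched.
* Test budgets are kept by construction: crops are a few thousand pixels and
  the acceptance cohort renders 60 faces in seconds; nothing is downscaled at
  test time relative to the stated world.

## Limitations

Beyond the generator's non-goals above: the method assumes a frontal,
single-face image with both eyes open; it reports a scalar asymmetry, not a
deviation angle in prism diopters nor a strabismus subtype; very light irides
weaken the dark-mask assumption (the HSV bound adapts to mean brightness but
the iris must still be the darkest coherent region); and a symmetric
*bilateral* deviation would by construction leave $S \approx 1$ — the
statistic screens for asymmetry, which is its clinical intent.
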