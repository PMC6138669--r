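---
title: "Methods: spectrum estimation, IPCL segmentation and triangle-region staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectrum estimation, IPCL segmentation and triangle-region staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsei)
```

## Overview

`hsei` implements a hyperspectral endoscopic imaging (HSEI) workflow for
oesophageal neoplasia screening. Conventional endoscopes deliver 8-bit sRGB
frames; the package estimates, for every pixel, a visible reflectance
spectrum (380--780 nm), and builds two downstream analyses on top of it:

1. **IPCL segmentation** — automatic extraction of intraepithelial
   papillary capillary loop (IPCL) pixel coordinates from narrow-band
   imaging (NBI) frames by a thinning-based pipeline, and
2. **triangle-region staging** — assignment of an IPCL neoplasia grade
   from the first two principal-component scores (FPC, SPC) of the
   sampled spectra, using per-stage triangles in score space.

Clinical image archives for this application are not publicly deposited,
so the package ships a first-class synthetic-fixture module that generates
every input the pipeline needs: colour checkers, a trichromatic camera
model, tissue-class spectra, and endoscopic scenes with planted vessel
patterns. All validation in the test suite runs against these fixtures.

## Spectrum estimation model

A reflectance spectrum $r(\lambda)$ sampled on the 81-point grid is
approximated in a low-dimensional PCA basis fitted to a spectral library:

$$\hat r = \bar r + \sum_{j=1}^{k} c_j \, v_j,$$

where $\bar r$ is the library mean, $v_j$ are orthonormal principal
components and $c_j$ the coefficients. Smooth visible reflectances are
classically low-dimensional, so the default is $k = 6$ (configurable);
every exactness test in the suite uses spectra constructed inside a
3-dimensional smooth family with $k = 3$, because a three-channel camera
determines at most three independent coefficients per pixel — for
$k > 3$ the per-pixel inverse problem is underdetermined and exact
recovery is impossible in principle, not merely numerically. This is a
deliberate validation design: the package's own recovery claims are made
where the mathematics allows them to be sharp.

The estimation chain per pixel is:

1. **sRGB decode** (IEC 61966-2-1 piecewise transfer) to linear RGB;
2. **chromatic adaptation** between the camera's scene white and the
   spectrophotometer's measurement white — a Bradford sharpened-cone
   von Kries transform, expressed in linear RGB by conjugating the 3×3
   XYZ map with the standard sRGB matrix. Bradford was chosen as the
   field standard for camera characterisation; when the two whites agree
   the map is the identity;
3. **third-order polynomial expansion** of the adapted RGB into all 20
   monomials of total degree ≤ 3 (the order is frozen and serialized
   with every model so coefficient files are portable);
4. a **transformation matrix** (k × 20, least squares on ≥ 20 checker
   patches) mapping features to basis coefficients;
5. reconstruction $\bar r + V^\top c$, clipped to $[0, 1.2]$.

The clipping band extends above 1 on purpose: estimates above unit
reflectance are physically impossible and indicate calibration failure,
so they are surfaced through the `n_clipped` attribute rather than
silently saturated at 1.

Targets for the polynomial regression may be XYZ tristimulus triples
(classical colour correction) or basis coefficients directly; both share
the same feature expansion. Whether one chains RGB → XYZ → spectrum or
regresses RGB → coefficients directly is a genuinely open design choice;
the package implements the direct chained path (`fit_hsei_model()`),
which keeps the per-pixel cost at one 20-vector product and avoids a
second fitted stage.

Least squares is solved by QR; designs with condition number above
1e12 fall back to a Moore–Penrose pseudo-inverse, and genuinely
rank-deficient designs raise an error naming the rank, because a
deficient checker cannot identify the map and silently regularising
would hide that.

### Colorimetry

The CIE 1931 2° observer is evaluated from the published multi-lobe
piecewise-Gaussian analytic fit rather than a lookup table; its ~1%
accuracy is irrelevant to every property checked here (white
normalisation, linearity, adaptation consistency), which hold for any
fixed observer. XYZ integration normalises a perfect reflector to
$Y = 100$. The default scene illuminant is equal-energy (a stand-in for
a broadband endoscope lamp); a daylight-like 6504 K blackbody spectrum is
available so checker measurement and scene capture can use genuinely
different whites, exercising the adaptation step for real.

## IPCL segmentation

NBI frames show IPCLs as dark curvilinear structures on brighter mucosa.
The automatic circling chain is:

grayscale (luma 0.299/0.587/0.114) → min–max contrast rescaling
$(p - \min)/(\max - \min) \times 255$ → Otsu binarization → inversion
(vessels become foreground) → Guo–Hall thinning → 8-connected component
circling → coordinate recording.

Numerical conventions, all of which matter for bit-reproducibility:

* Rounding at 8-bit boundaries is half-up (127.5 → 128); internal maths
  is floating point.
* The binarization level is chosen by Otsu's between-class-variance
  criterion on the 256-bin histogram (first maximum on ties). A fixed
  0.5 level fails on dim NBI frames; the data-driven threshold is logged
  in the output metadata.
* Thinning is the parallel two-subiteration Guo–Hall algorithm iterated
  to a fixed point, implemented vectorised over shifted neighbourhood
  masks; the test suite checks it against an independent per-pixel loop
  reference, and checks idempotence, skeleton ⊆ foreground, and
  preservation of 8-connected component counts on random blobs.
* Components smaller than `min_size` (default 5 px) are dropped as salt
  noise.
* Coordinates are exported 0-based, (row, col), in row-major sorted
  order — an unambiguous round trip with array indexing. When the
  skeleton holds at least `budget` pixels (default 1000, the
  conventional per-frame sample), a seeded uniform sample without
  replacement of exactly `budget` points is taken; otherwise all pixels
  are returned with a warning.

## Triangle-region staging

Spectra sampled at IPCL coordinates are projected onto the first two
principal components of a mean-centred PCA (`fit_score_chart()`); a
patient's testing point is the mean of the per-pixel scores, which by
linearity equals the score of the mean spectrum (both are computed and
asserted to agree).

For each stage, a triangle region is fitted as the **maximum-area
triangle** over that stage's score cloud. Since the maximising vertices
are extreme points, the search is restricted to convex-hull vertices and
is exhaustive over hull triples — a deterministic superset of both a
manual "three peripheral points" choice and a randomized area-comparison
search; ties are broken lexicographically on sorted vertex coordinates,
and manually chosen vertices can be supplied instead. Membership of a
testing point $U$ in triangle $DEF$ uses the area-sum identity

$$\Delta UDE + \Delta UEF + \Delta UDF = \Delta DEF,$$

with each area computed as half the absolute determinant of the edge
vectors. Two numerical points deserve note. First, the equality case is
read as *boundary-inclusive membership* (a point on an edge or vertex is
inside): reading the equality as "edge of or outside" would contradict
the strict-inequality characterisation of exterior points, so the
package documents and implements the only self-consistent convention.
Second, exact floating-point equality is unattainable, so the test is
$\sum \Delta \le \Delta DEF \,(1 + \varepsilon)$ with relative tolerance
$\varepsilon = 10^{-9}$ by default.

Regions are tested in severity-descending order — IPCL-V3 SCC,
IPCL-V1 SCC, IPCL-V1 HGD, IPCL-IV — so a point in an overlap is assigned
the more severe stage; a point in no region is `undetected`. The order is
configurable. Per-stage performance is summarised one-vs-rest:
sensitivity TP/(TP+FN) and specificity TN/(TN+FP), with `undetected`
counting as negative for every stage.

Published clinical score ranges for these stages are data-dependent
properties of a particular cohort; they are deliberately not hard-coded
anywhere and cohort-level diagnostic rates are out of the package's
validation scope (the underlying images are not public). What the tests
do establish is *parameter recovery*: on synthetic score clouds with
disjoint class triangles, sensitivity and specificity are exactly 1.0
for all four stages, and when a higher-priority triangle is made to
cover a fraction $f$ of a lower-priority class region, that class's
sensitivity drops by $\approx f$ (within binomial error at 500 points
per class).

Whether a patient's score should be computed from all pixels or only
IPCL-sampled pixels is ambiguous in general; the package supports both
and the pipeline defaults to IPCL-sampled pixels for NBI frames, since
the vasculature is what carries the staging signal there.

## The synthetic-fixture generator

`make_tissue_spectrum()` draws class spectra as smooth Gaussian-bump
mixtures (a fixed 3-component family: broad lightness, blue–red tilt,
and a narrow 530 nm band tracking haemoglobin absorption) with
severity-scaled amplitudes plus i.i.d. noise of sd 0.01. The class mean
levels encode the expected clinical ordering:

* white light: reflectivity strictly *decreasing* normal → dysplasia →
  dysplasia-ECA → ECA (lesions are darker red than surrounding mucosa);
* Lugol staining: strictly *increasing* with severity (glycogen-rich
  normal mucosa stains dark, neoplasia stays unstained and bright);
* NBI: the four IPCL grades darken with grade, separated in mean by
  ≥ 0.05 reflectance units.

`make_endoscopic_scene()` modulates the class mean by a smooth ±10%
multiplicative texture/illumination field plus 1% pixel noise, and for
non-normal NBI stages stamps 5–20 vessel strokes (seeded self-avoiding
random walks of length 30–80, width 1–3 px) at 0.35× the local
background brightness, recording them in a ground-truth mask. The walk
generator is tuned to produce strokes whose skeletons are recoverable at
1 px, which is exactly what the segmentation recovery test measures.
`make_color_checker()` produces either free random smooth patches (rich
rank, for basis fitting) or patches confined to the fixed rank-3 family
(for exact-recovery validation); in the rank-3 branch the coefficient
box is scaled so no patch touches 0 or 1, because clipping would break
the exact low-rank structure the recovery argument relies on.

What the fixtures deliberately do **not** model: realistic mucosal
texture, specular highlights, vignetting, NBI's proprietary colour
reproduction, or magnification effects. Passing tests therefore
demonstrate correctness of the algorithms under their stated
assumptions, not clinical performance on real endoscopy.

## Problem sizes and reproducibility

The test suite and the acceptance script run at desk scale chosen to
keep each property sharp: 30-patch checkers (the classical checker
size), 100-spectrum round trips, 96×96 scenes for segmentation recovery
(four seeds pooled), a 256×256 dense-vessel scene for the 1000-point
budget check, 500 points per class for classifier recovery, and 64×64
scenes across a 12-scene pipeline for the byte-identity re-run check.
Every random draw flows from an explicit integer seed; fixture
generation saves and restores the caller's RNG state. Pipeline outputs
carry a provenance block (config, input hashes, package version) that
intentionally omits wall-clock timestamps so that re-running an
unchanged pipeline is byte-identical.

## Worked example

```{r example, eval = FALSE}
cam <- camera_model()
checker <- make_color_checker(30, seed = 1, rank = 3)
model <- fit_hsei_model(checker, render_rgb(checker, cam, bits = NULL),
                        k = 3)

scene <- make_endoscopic_scene("IPCL_V3_SCC", "nbi", size = c(96, 96),
                               seed = 7)
img <- render_rgb(scene, cam)
seg <- segment_ipcl(img, budget = 1000, seed = 1)
nrow(seg$coordinates)        # recorded IPCL coordinates
autoplot(checker)            # the calibration spectra
```

## Known limitations

* Spectra are estimated only on 380–780 nm; no radiometric (absolute)
  calibration is attempted.
* Exact spectral recovery holds only for spectra inside the fitted
  basis span imaged through a noise-free continuous-valued camera; 8-bit
  quantisation alone contributes ≈ 2–3 × 10⁻³ RMSE.
* The maximum-area triangle search is O(h³) in the number of hull
  vertices — exact and fast for per-stage patient clouds (tens of
  points), not intended for thousands of hull points.
* Guo–Hall thinning can erase degenerate 2×2 structures; the component
  preservation guarantees are validated for vessel-scale shapes.
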