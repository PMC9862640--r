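---
title: "Methods: the cocoonsort sorting pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the cocoonsort sorting pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cocoonsort implements the computation behind a multi-station optical machine
that sorts silkworm cocoons into quality classes. This vignette explains each
model, its assumptions, the parameters that matter, the numerical choices we
made where the design was genuinely open, and what the synthetic benchmark
does and does not demonstrate.

## Segmentation and the size gate

A cocoon sits roughly centered in a cradle, photographed against a darker
background. Segmentation works on the HSB representation (all three channels
rescaled to 0–255) through the edge-emphasis map

$$M = \log\!\big(\,|0.2989\,H + 0.5870\,S + 0.1140\,B| + \varepsilon\big).$$

The brightness channel tracks illumination changes across the silhouette edge
while hue and saturation separate cocoon surface from background; the BT.601
luminance weights give a single scalar field and the log compresses its
dynamic range. Note the weights are applied to the HSB channels, not to RGB —
an unusual but deliberate choice of the machine's imaging protocol, kept here
as specified. $\varepsilon$ (config key `imaging.eps`, default $10^{-6}$)
guards $\log 0$ on black pixels; it only affects pixels whose weighted sum is
near zero and is far below the quantization step everywhere else.

$M$ is normalized to its maximum, quantized to 8 bits, and thresholded with
an exact integer Otsu: the threshold is the argmax of between-class variance
over the 256-bin histogram, ties resolved to the smallest threshold. A
constant map is rejected as degenerate rather than binarized arbitrarily.
Which side of the threshold is "cocoon" is decided by the class of the
image-center pixel (the cocoon is centered by construction of the machine);
`imaging.polarity` can force either side. The largest 8-connected component
is kept and holes are filled — 4-connectivity would fragment diagonal
boundaries, so components are 8-connected throughout the package.

The size station counts foreground pixels and applies a strict acceptance
band: `size.min_px2` < area < `size.max_px2`, boundary values rejected. The
defaults (81,900 and 124,500 px²) are the machine's operating thresholds at
its reference optics, equivalent to the 300–450 mm² band of normal cocoons
at the calibration `size.px2_per_mm2 = 273`. The calibration is exposed in
the configuration because it is purely a property of lens and working
distance; the synthetic benchmark generator writes a config with these three
values rescaled to its own rendering scale.

## Outline digitization

The silhouette outline is sampled as 180 points, one per $\pi/90$ rad, by
casting rays from the region centroid and recording the **outermost**
crossing of the (bilinearly interpolated) mask boundary, located to sub-pixel
precision by linear interpolation to the 0.5 level. Taking the outermost
crossing keeps waisted, peanut-shaped cocoons representable where a ray cuts
the boundary more than once; the scheme still cannot represent shapes whose
outline doubles back around the centroid (extreme malformations), and a
centroid falling outside the region raises a digitization error rather than
producing a nonsense polygon.

Radial sampling fixes the outline parameterization to the polar angle. For
an eccentric ellipse this differs from an equal-arc-length sampling, which
slightly redistributes spectral mass across harmonics (a pure ellipse
digitized this way carries about 98–99% of its power in harmonic 1 rather
than 100%). This is a property of the digitization scheme, shared by every
outline consistently, and therefore harmless to classification.

## Procrustes alignment

Outlines are superimposed by generalized Procrustes analysis: each 180-point
configuration is centered, scaled to unit centroid size, and iteratively
rotated onto the evolving mean shape (rotation by SVD, reflections
disallowed), with the mean recomputed each pass until the summed squared
residual changes by less than $10^{-8}$ relatively, or 200 iterations.
Removing scale is a design decision: cocoon size is gated by its own
station, so shape features should be size-free. New outlines at prediction
time are aligned to the frozen mean shape by ordinary Procrustes
superimposition, making training and prediction geometry identical.

## Elliptic Fourier descriptors

The closed outline's x and y coordinate series are expanded in Fourier
series with four coefficients per harmonic up to the Nyquist limit (half the
point count, 90 for 180 points); the harmonic power is
$(a_i^2+b_i^2+c_i^2+d_i^2)/2$.

Two parameterizations are implemented. The default treats the 180 points as
equally spaced in the curve parameter and computes coefficients by the
discrete Fourier transform of the coordinate series. For outlines digitized
at equal angular spacing the chords are nearly uniform, so this matches the
classical chordal convention closely, and it makes the decomposition an
exactly invertible transform pair: reconstruction from all Nyquist harmonics
reproduces the input points to machine precision, harmonic powers satisfy
Parseval's identity against the signal power of the coordinate series, and
analysis inverts the synthetic generator's band-limited shapes exactly.
These exactness properties are what the test suite pins down (round-trip RMS
below $10^{-3}$ px, power conservation below $10^{-9}$ relative). The
classical chord-length closed-form integrals over the piecewise-linear
outline are retained as `method = "chord"` for comparison with the
morphometrics literature; they carry an $O(1/N^2)$ piecewise-linear
truncation bias instead of being exact, and the two conventions agree to a
few percent on digitized cocoon outlines.

The series is truncated at the smallest k whose average cumulative power
over the training outlines reaches `shape.power_fraction` (default 99.999%)
of the average total power; k is frozen into the fitted shape model. No
harmonic-1 normalization is applied, since orientation and scale are already
removed by the alignment step.

## Classifiers

Both decision models (shape, alive/dead) are unpenalized maximum-likelihood
logistic regressions on Z-scored features, $(X-m)/s$ with population
standard deviations (the choice between population and sample denominators
is immaterial downstream of a logistic fit, but it is explicit and
configurable). A constant feature is an error by default; the shape model
drops exactly-constant coefficient columns, which arise when the digitizer's
fixed starting ray pins a sine term across the whole set.

Degenerate fits are handled, not hidden: when the classes are linearly
separable (or the design is rank-deficient, as happens at very small sample
sizes), the unpenalized likelihood has no finite maximizer and the fit falls
back to a ridge-penalized iteratively reweighted least squares with
$\lambda = 10^{-8}$, with a warning. The penalty is small enough to leave
predictions unchanged while keeping the weights finite. Prediction
thresholds the probability at 0.5 (configurable); a probability exactly at
the threshold goes to the positive class, so the tie-break is deterministic
and documented.

Training protocol, mirroring the machine's: balance the two classes by
undersampling the majority class without replacement; split stratified with
largest-remainder apportionment so the training size is the half-up-rounded
fraction of the total (70% for shape, 80% for alive/dead); fit standardizer
and model on the training part only. Monte Carlo cross-validation repeats
balance–split–fit–evaluate with per-iteration seeds derived from a master
seed; `balance = "once"` (balance a single time, re-split each iteration) is
the default, `"per_iteration"` redraws the majority subsample every round —
the two differ in whether the majority subsample is treated as part of the
dataset definition or of the resampling, and both are legitimate readings of
a balanced-then-validated protocol, so both are provided.

Stations report overall accuracy $A = (T_p+T_n)/(T_p+T_n+F_p+F_n)$ and
recall $R = T_p/(T_p+F_n)$ with defects as positives; reported percentages
round half away from zero to one decimal, recall to two.

## Stain detection

Each stain camera has a fixed HSB box (`stain.top`, `stain.bottom` in the
configuration; defaults H 0–80/S 60–255/B 0–255 and H 0–255/S 220–255/B
0–255 respectively, reflecting their different illumination) and flags
pixels whose three channels all fall inside it. The verdict applies a
**per-object** rule: the cocoon is stained when any single 8-connected
flagged object's area strictly exceeds `stain.min_area_px2` (144 px² at the
reference optics). Summing object areas would flag accumulations of speckle
noise, so we deliberately do not. Filtering is confined to the segmented
cocoon region by default (`stain.roi`), because background and cradle pixels
can satisfy the saturation thresholds; the restriction can be switched off.
The two views are OR-combined — a spot on the face away from one camera is
exactly the case the second camera exists for — and pairing is by the
progressive acquisition id, with a mismatch raising an error.

## The photodiode station

One acquisition is a 7×5 matrix of 10-bit ADC counts read row-first, flattened
row-major into a fixed 35-channel feature vector. "Alignment" of the channels
is positional: each cocoon yields one static frame, so no temporal
registration exists to be done — this is an interpretation, recorded here.
Dead is the positive class (the station exists to discard dead cocoons). No
dark-frame subtraction is applied; the configuration leaves a hook for it,
and the Z-score absorbs any global affine drift of the ADC scale, which the
tests assert directly.

## The synthetic benchmark

No image or sensor corpus ships with the machine, so the package carries a
generator that makes every station testable with exact ground truth.
Silhouettes are parameterized directly in elliptic Fourier space:
well-shaped cocoons are ovoids of aspect ratio about 1.45–1.65 with faint
higher harmonics; bad-shaped cocoons get a pronounced waist via the radial
perturbation $r \to r(1 - w\cos 2t)$, $w \in [0.28, 0.40]$, which lands on
harmonics 1 and 3 — so the defective class is "extra power in harmonic 3",
controllable and realistic in kind. Stains are discs of specified physical
area (2–5 mm²) in colors inside the camera profiles; pupa frames are
two-class Gaussians over the 35 channels with a between-class shift of
`separation` pooled standard deviations per channel (default 3; the dead,
desiccated pupa transmits more light — the sign is a modeling choice and
only its magnitude matters to the classifier). All randomness fans out from
one master seed through per-item hashed seeds, so any subset regenerates
independently and byte-identically.

The generator emulates the machine's acquisition layout (one BMP folder per
camera, sensor CSV, timestamp–camera–progressive-number filenames) at a
configurable optical scale. Scaling is physical: pixel areas scale with the
square of the scale factor, and the written configuration rescales the size
band, the calibration, and the stain object-area rule accordingly (144 px²
at the reference optics is about 0.53 mm²; a fixed 144 px² at quarter scale
would demand stains larger than some whole cocoons). Benchmarks in the test
suite use scale 0.2–0.25 — images of roughly 260×190 to 320×240 px — with
150 cocoons for training and 600 (six categories of 100) for the sorted
benchmark; these sizes were chosen as the smallest at which every station
operates in its intended regime.

What passing on this benchmark shows: the chain of segmentation,
digitization, alignment, decomposition, thresholding, classification,
routing and evaluation is internally correct, exactly separable stations
(size, stain) are solved exactly at zero noise, and the whole pipeline is
deterministic under a fixed seed. What it does not show: performance on real
cocoons. Real images have surface texture, shadows, cradle reflections,
non-uniform illumination, and — the machine's dominant real failure mode —
cocoons standing vertically in the cradle so their projected area
misrepresents their size. The generator models none of these; its optional
Gaussian brightness texture is a smoke test for robustness, not a lighting
model.

## The sorting cascade

Selection evaluates **all** enabled stations for every cocoon (so reports
cover rejected cocoons too) but routes on the **first** failure in the
machine's physical order: size → shape → stains → vital, to the routes
`discard:size`, `discard:shape`, `class:stained`, `class:dead`, else
`grade:first`. The machine's literature speaks of first-to-third manual
grades without mapping them to stations; we mirror stations in the route
vocabulary instead of inventing grade semantics. Records missing a station
input are flagged incomplete, excluded from metrics, and reported. Pixel
coordinates are 0-based, row-major, origin top-left, everywhere.

## Known limitations

- The radial digitizer cannot represent outlines that are multi-valued
  around the centroid beyond what the outermost-crossing rule captures.
- The Otsu polarity heuristic assumes the cocoon covers the image center;
  off-center framing requires forcing the polarity.
- The shape classifier's accuracy depends on class structure the generator
  plants; nothing here estimates real-world shape separability.
- Dataset bookkeeping of the machine's own validation campaign (sample
  counts across stations) is not modeled; the package is size-agnostic.
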