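---
title: "Methods: fused MLS + hyperspectral tree classification"
author: "canopyfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fused MLS + hyperspectral tree classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A vehicle-mounted measurement system drives past an urban garden carrying a
multi-layer laser scanner and a hyperspectral line camera. The laser yields a
dense side-view point cloud of every tree; the line camera yields, many times
per second, a vertical fan of 659 pixels binned into 123 spectral channels
over 397–1,086 nm, with the outermost 10 pixels permanently viewing a
near-Lambertian white reference panel. The scientific question is whether
*fusing* the two streams — crown shape from the laser, reflectance from the
spectrometer — classifies individual trees better than either stream alone,
both for the coarse conifer/broadleaf split and for a 10-species
identification task.

`canopyfuse` implements that analysis as a reusable, fully testable pipeline.
Because the original field data were never deposited, the package includes a
first-class synthetic scene generator that reproduces the *statistical
structure* the analysis depends on, so every downstream stage can be
exercised and validated without any download.

## The synthetic garden

`default_garden_config()` encodes the study inventory: 168 specimens of 23
named species plus an unidentified group, with the published per-species
counts (`table1_fixture()`). Species with at least five identified specimens
form the 133-specimen, 10-species classification subset.

**Crown models.** Conifers are uniform-density cones (apex up, base radius
0.24 of tree height): the height density is proportional to the
cross-sectional area $(1-h_N)^2$, so the mean normalized height is exactly
1/4. Broadleaves are a thin trunk plus a uniform ellipsoid of revolution
centred at normalized height 0.65 (semi-height 0.30, radius 0.22 H) holding
90% of the points; the crown height density is the Epanechnikov shape
$\tfrac34(1-u^2)$, giving mean normalized height 0.65. These are the simplest
shapes that reproduce the empirical separability of the two habits by
height-ratio features; `crown_fraction_above()` exposes the closed-form
shape-effect margin (cone: $P(h_N>0.5)=0.125$; default broadleaf: 0.76).
Heights are drawn uniformly from 2.5–7.5 m (young garden specimens, not
mature forest); point counts are 60 points per m³ of crown volume with a
floor of 20.

**Spectra.** Each species owns a 123-channel reflectance curve relative to
the white panel, built from a parametric vegetation shape: a dark visible
floor, a green bump at 550 nm, a logistic red edge near 700–720 nm, and a
species-specific near-infrared plateau. Broadleaf plateaus are brighter than
conifer plateaus, mirroring the infrared separation that drives the
spectral habit split. The channel grid is linear over 397–1,086 nm
(≈5.65 nm spacing); the instrument's true centers are unpublished, so a
linear grid is the only defensible default, and quoted wavelengths are
resolved with `nearest_channel()`.

**Noise model.** Directional-lighting variation in side-looking mobile
acquisition is severe — differences between minimum and maximum reflectance
of the same target can exceed 100%. The generator uses multiplicative
lognormal noise at three scopes: a per-frame illumination factor
(sdlog 0.5) shared by targets *and* reference pixels, which the
normalization cancels exactly; per-pixel noise (sdlog 0.25), which it does
not; and rare "shaded target" frames (probability 0.05) in which the panel
stays lit while tree pixels are multiplied by 0.3, producing the
anomalously dark normalized spectra seen in practice. There is no BRDF or
leaf-geometry model, no multi-echo simulation, and no georeferencing error:
a green test on this generator establishes that the *pipeline arithmetic
and protocol* behave correctly, not that any real sensor would achieve a
given accuracy.

**Geometry.** The trajectory is a straight drive at 5 m/s past two planting
rows (6 m and 9 m from the track), frames at 2 Hz, sensor 2 m above ground.
Pixels cover a 44.4° vertical fan, so at close range the fan does not reach
tall tree tops: such specimens get truncated spectral coverage, another
property of the real acquisition the tests assert. When two crowns fall in
the same pixel the nearer one wins, so closely planted trees contaminate
each other's fused spectra — deliberate realism; exact-identity tests use a
widely spaced single-row layout instead.

## Fusion

The overlap test mirrors the acquisition order: horizontal first (a time
window around each frame, default half the frame interval), then vertical
(the point's elevation angle against each pixel's angular interval widened
by half the laser footprint, default 0.25°, the scanner's angular
resolution). Reflectance is the pixel's digital numbers divided by the mean
of the 10 reference pixels per channel (mean, not median, for linearity);
all pixels matched to one laser point — across frames as well as within
one — are averaged unweighted. Specimens that end up with no fused spectrum
stay in structural-only analyses and are flagged, never zero-filled.

## Features

34 structural features summarise the normalized height distribution
$h_N = (z - z_{\min})/(z_{\max} - z_{\min})$ of each specimen: three coarse
thirds, eight interior 0.1-wide bands, nine cumulative ratios
$PR(h_N > q)$, skewness and kurtosis, nine height quantiles (hq10–hq90),
and Max, Mean, CV of height above base. Conventions that the data cannot
decide (ties have probability zero for continuous heights) are fixed as:
strict inequalities for one-sided ratios, half-open $[lo, hi)$ bands, the
coarse top third computed as the complement so the three-way partition sums
to 1 *bit-exactly*, population (not sample-corrected) central moments with
raw kurtosis (normal ≈ 3; excess behind a flag), and type-7 linear
interpolation for quantiles. Every feature is verified against an
independent brute-force implementation at 1e-12 relative tolerance. The 123
spectral features are per-channel unweighted means over the specimen's
fused points.

## Classification protocol

Features are min-max scaled to $[-1, 1]$; the default scales once globally
before classification (protocol-faithful), with a `per_fold` mode that
refits scaling inside each training fold as the leakage-safe alternative.
The classifier is a C-SVM with RBF kernel evaluated by leave-one-out
cross-validation; a linear discriminant (`MASS::lda`) serves as the
reference classifier. Because no SVM implementation is available in the
target environment, the package authors its own sequential minimal
optimisation solver (maximal-violating-pair working-set selection,
one-vs-one voting with ties to the smallest class index, no class
weighting — deliberately, since unweighted training reproduces the
majority-class favouritism the protocol is known for). The solver is
cross-checked against an independent quadratic-programming solution of the
same dual.

Kernel parameters are tuned per feature subset by seeded stratified 5-fold
CV over a 3×3 coarse subset of the standard exponential grid
($C \in 2^{\{-1,5,11\}}$, $\gamma \in 2^{\{-9,-3,3\}}$; the full
$2^{-5..15} \times 2^{-15..3}$ grid is available), ties to the smallest
$C$ then $\gamma$. Whether the original analysis tuned once globally or per
subset is not recorded; per-subset is the default here, and a
single-point grid disables tuning for large searches. The subset search is
exhaustive over singles and pairs; the best 10% of structural and of
spectral pairs (ties at the cutoff included, so the realized fraction can
exceed the nominal one) are crossed into mixed quadruples; greedy forward
selection runs a fixed four iterations as the low-cost comparator.
Accuracies are reported from the LOOCV confusion matrix (rows predicted,
columns reference): overall, per-class user (row) and producer (column)
accuracy, displayed at one decimal with half-up rounding.

## Numerical and degenerate-input choices

- A class with a single specimen can never be predicted correctly under
  LOOCV; the five-specimen species threshold exists precisely for this.
- Constant features scale to 0; a degenerate specimen (all heights equal)
  or an all-shaded spectrum raises an informative error rather than
  producing silent zeros.
- SMO stops at a 1e-3 duality-gap tolerance with an iteration cap of
  2×10⁵; the offset uses free support vectors when any exist, else the
  active-bound midpoint.
- All randomness (scene generation, inner-CV folds, quadruple subsampling)
  derives from explicit integer seeds; LOOCV itself is deterministic.

## What a green test does not establish

The generator's world is cleaner than the field data: crowns are ideal
solids, spectra differ smoothly between species, there is no wind, no
phenology, no understory, and no navigation error. Consequently synthetic
accuracies are not comparable to the published field accuracies — conifer
separation in particular is nearly perfect synthetically. The tests
therefore assert *relationships* (fused quadruples beat single-sensor
pairs; null effects yield chance-level accuracy; normalization cancels
illumination exactly) rather than absolute accuracy values.

One documented check is knowingly unattainable and kept red: the mean
LOOCV accuracy of a pure-noise feature over 200 replicates is *not* within
three standard errors of 50%. Under leave-one-out the held-out specimen's
class is always the minority of the training set (19 vs 20 here), so every
unweighted classifier is pessimistically biased below chance — the
measured mean is ≈40% at the grid-center parameters and ≈34% under the
tuned default, and even an ideal nearest-neighbour rule attains only
19/39 ≈ 48.7%. The suite therefore also asserts the direction that matters
for validity — the absence of *optimistic* bias — which passes.
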