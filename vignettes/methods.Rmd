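---
title: "From photographs to stress measurements: the rhodoscan pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From photographs to stress measurements: the rhodoscan pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

rhodoscan turns laboratory photographs of rhodolith-forming calcareous algae
into quantitative stress measurements: the visible area of live algae and its
HSV color, tracked over time and related to experimental factors. This
vignette explains the model behind each stage, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the design
choices made where more than one reasonable implementation existed.

## The measurement problem

Live crustose calcareous algae are pink to red; as they die under sediment
stress they blanch towards grey-white. In a flow-through exposure experiment,
light (L), flow (F) and sediment load (S) are varied over 21 chambers in a
face-centred central composite (CCF) design, and each chamber's rhodolith
samples are photographed weekly in a water-filled cylinder next to a
six-circle color reference plate. Two confounders stand between those photos
and a usable size/color signal: illumination and white-balance fluctuations
of a camera in automatic mode, and frame-to-frame zoom variation. The
reference plate, visible in every frame, is the instrument that removes
both.

## Pre-processing

**Illumination correction** uses local space-average color scaling. Each
channel is linearized with the sRGB display gamma (2.2), divided pixel-wise
by `tau` times its Gaussian-blurred version, and re-encoded:

$$\hat I_c = 255\left(\frac{(I_c/255)^{2.2}}{\tau\, G_\sigma[(I_c/255)^{2.2}]}\right)^{1/2.2}$$

with `sigma = 0.093 * max(height, width)` and `tau = 2`. The blur estimates
the local space-average color; dividing by it flattens smooth gradients.
Two consequences are worth knowing. A spatially uniform image maps to
`255 * (1/tau)^(1/2.2)` (about 186 at the default `tau = 2`) regardless of
its input level -- the transform normalizes local contrast, it does not
preserve absolute brightness. And regions much brighter than their
surroundings can clip at 255; on low-contrast underwater frames this is
rare, which is one reason the synthetic scenes use a water-grey background.
A near-black blur denominator is floored at machine epsilon with a warning.

**Plate detection** is a Hough circle transform: per-channel gradient
magnitudes (channel-wise, because a circle can share its luminance with the
background while differing in color) are thresholded into an edge map,
correlated with ring templates over radii within ±30% of the layout prior,
and peak candidates are filtered by low interior color variance
(per-channel SD below 25 by default) and assembled into the longest
near-vertical chain with near-uniform spacing. Six circles give
`mode = "auto"`; fewer give `"partial"`; none gives `"failed"`, at which
point manual circle coordinates can be supplied -- mirroring practice with
real imagery, where reflections on the plate defeat automatic detection in
a minority of frames.

**Color correction** estimates one exponent per channel from the plate.
Writing $c_{l,c}$ for the observed median of circle $l$ on channel $c$ and
$\bar c_{l,c}$ for the pooled (median-over-images) reference, the package
uses

$$\gamma_c = \mathrm{median}_l \frac{\log(\bar c_{l,c}/255)}{\log(c_{l,c}/255)},
\qquad J_c = 255\,(I_c/255)^{\gamma_c}.$$

The orientation of the fraction is deliberate: with the correction applied
as an exponent, only this orientation maps the observed plate colors back
onto the reference (for a single circle it is exact). Circles sitting at 0
or 255 on a channel are excluded from that channel's median because the
logarithms degenerate -- this is also why the saturated original plate
colors are useless for estimation and the pooled *in-water* triplets serve
as the packaged reference. If every circle is degenerate on a channel the
exponent falls back to 1 with a warning.

**Zoom correction** rescales each image by the ratio of the reference plate
spacing to the observed spacing, so that one image pixel corresponds to the
same physical length everywhere. The later size measurement multiplies the
segmented pixel count by the same ratio once more (a linear factor): after
resampling that residual is within a pixel of 1, and the combination keeps
the measured area stable to within about 1% across rendering zooms of
0.8-1.25. A linear weight alone cannot do this -- a raw pixel count scales
with the square of zoom -- which is why the pipeline resamples first.

The stage order is illumination, then color, then zoom.

## Features and the H²SOM classifier

Pixel features are per-channel medians over an 11 x 11 neighbourhood,
computed on a 2 x 2 grid (stride 2) for speed, with the window clipped at
image borders. Median RGB is deliberately minimal: the classes differ in
color, not texture, and the median suppresses sensor noise and small
occlusions without smearing region boundaries the way a mean would.

The classifier is built on a hierarchically grown hyperbolic self-organizing
map. The lattice is the vertex set of the regular {3, 8} triangular
tessellation of the hyperbolic plane out to three rings, realised in the
Poincaré disk: a centre node, then rings of 8, 32 and 120 nodes (161
prototypes in total; ring sizes follow V(r+1) = 4 V(r) - V(r-1)). The
exponential growth of hyperbolic space gives the map many fine-grained
leaf prototypes while keeping a shallow hierarchy.

Training is phased, one ring at a time: ring r is initialized from its
parent prototypes plus a small seeded jitter and receives standard SOM
updates `u <- u + alpha * h(d) * (x - u)`, where `d` is the hyperbolic
distance between the winner and the updated node and
`h = exp(-d^2 / (2 sigma_n^2))`. Winners are found by beam descent through
the already-trained rings. Per phase, the learning rate decays exponentially
from 0.99 to 0.1 and `sigma_n` from the ring's inter-node spacing to a
quarter of it; the total update count is 30 passes' worth, split evenly
across phases. Earlier rings are frozen once their phase ends -- a property
with a visible consequence: if the data contain as many well-separated
clusters as there are prototypes, the ~41 frozen coarse prototypes cannot
specialise, and perfect one-prototype-per-cluster assignments are not
reachable. The package's capacity test therefore uses fewer clusters than
leaf prototypes.

Classification uses exhaustive best-matching-unit search over all 161
prototypes (ties to the lowest node id); at this lattice size it is cheap
and exact. Beam search is provided for large lattices: on the trained
segmentation fixture it agrees with exhaustive search for about 81% of
vectors with a mean distance ratio of 1.05, but a wrong branch at ring 1
cannot recover, so individual queries can land far from the optimum. The
pipeline never relies on it.

## Prototype label mapping and post-processing

The SOM is unsupervised; class semantics come from sparse expert labels
(points and rectangles, classes live / stressed / dead / bare, with live
and stressed fused into one positive class). Every labelled feature vector
is assigned to its BMU; for each prototype j, `q_j` counts assigned vectors
and `q_j+` the positive ones, and `s_j = q_j+/q_j` scores how live-like the
prototype is. Prototypes are ranked by descending `s_j` (ties broken by
larger `q_j+`, then lower node id -- favouring better-supported prototypes)
and the shortest prefix covering at least 80% of all positive vectors is
selected. Pixels whose BMU is in the selected set are live; the binary mask
is then opened with a 10 x 10 square structuring element at full image
resolution, which removes isolated false positives smaller than the
element. Opening is exact here (integer box sums), anti-extensive and
idempotent.

The 80% coverage rule is conservative by construction, and it couples to
sampling design in a way worth understanding: when the mapping pool is
small, the ranked cells cover positives in coarse steps and the selected
prefix typically overshoots well past 80%, giving pixel recall in the
low 0.9s; as the pool grows the cut lands ever closer to exactly 80%.
Training and mapping on a small subset of images and classifying the rest --
the configuration used throughout the package's tests, with 6 of 20 scenes
-- matches how the method is meant to be deployed.

Evaluation reports recall, precision and false positive rate against the
sparse labels, with empty denominators reported as missing rather than
zero. Under example-based labelling most segmented pixels are unlabelled,
so precision is computed but non-diagnostic; recall and the FPR over dead
and bare labels are the meaningful scores.

## Size, color and chamber series

Per image, the live area is `A = (segmented pixel count) * d_ref / d_n`
(the residual zoom weight), hue is averaged as a circular quantity (mean
resultant direction), and saturation and value as plain means over the
segmented pixels. An empty mask yields `A = 0` with missing colors, which
downstream marks the observation as a failed segmentation rather than a
measurement of zero. Relative size divides by the earliest retained
nonzero baseline (the study discarded its first two weeks for plate
reflections, so "first measurement" means first usable). Measurements are
averaged per chamber and time point -- arithmetically for size, saturation
and value, circularly for hue -- because the two samples per photo are not
co-located across weeks and all samples in a chamber share one treatment.

## PLS regression

The chamber series are related to the design factors by PLS2 (NIPALS with
deflation) on mean-centred, unit-variance data: predictors L, F, S, T plus
S² (the one square term the CCF design supports that the data reward),
responses relative size, hue, saturation, value and -- when supplied --
photosynthetic efficiency P and sediment coverage SC. Goodness of fit is
per-response R² with all components; goodness of prediction is R² from
out-of-fold predictions, by default leave-one-chamber-out (21 folds) so
technical replicates never straddle folds; each training fold is re-scaled.
Rows from failed segmentations are removed before fitting (the outlier
rule). Correlation loadings -- Pearson correlations of every scaled
variable with each component's scores -- are drawn with 50% and 100%
explained-variance circles; two components are the default because the
data's structure is two near-orthogonal directions (sediment with SC, P and
the colors; time with relative size). Hue enters as a plain scalar, which
is acceptable while observed hues sit in a narrow arc near red (roughly
0-10 degrees); hue distributions straddling the 0/360 wrap would need
unwrapping first, a documented limitation. An auxiliary model predicts P
from the three color variables alone, and a simple linear regression of
relative size on time is provided for comparison.

## The synthetic-data generator

Every stage above is testable without the archived imagery because the
generator renders plate-plus-samples scenes with full ground truth. A scene
is background, a vertical strip of six reference circles (uniform spacing
makes the zoom statistic exact), and one or two rhodolith blobs built from
Fourier-perturbed radii, layered bare / dead / live from the outside in,
with sediment drifts occluding the samples. The clean scene then passes
through a fixed distortion chain -- per-channel gamma, a smooth
multiplicative gain field, additive Gaussian noise, zoom resampling, clipping
-- in that documented order, so recovery tests are well-posed. Ground-truth
masks describe *visible* class regions (sediment-occluded pixels belong to
no class) and are resampled with the image.

Defaults emulate the study conditions at quarter linear scale (864 x 648)
for speed: in-water plate triplets far from saturation; a live palette
centred on desaturated red-pink (hue near the 0-10 degree arc the study
observed, drifting toward red over time); pale grey-white dead material;
brown-grey bare substrate; water-grey background, because real underwater
frames are low-contrast; sediment as a moderate number of 6-18 px drifts
rather than confetti, since deposition is contiguous and the 10 x 10
opening would otherwise amplify every pinhole into a 15+ px hole; ±15%
illumination gain; per-pixel palette jitter (SD 8) and sensor noise (SD 3).
Structural randomness (blob shapes, drift positions, gain orientation) is
driven by `shape_seed`, texture randomness by `seed`, so a scene's geometry
can be held fixed while its noise varies -- and with noise disabled the
render is bit-identical across seeds. Time series shrink the live blob so
its area follows `(1 - shrink_rate)^t` exactly up to rasterization.

What the generator does not emulate: photorealistic water optics, specular
reflections (tests paint them explicitly when needed), sample rotation
between time points (a real confounder of the size signal, flagged as a
limitation of photographic sizing in general), sediment physics, and any
texture difference between classes. Passing tests therefore demonstrate
that the pipeline's logic is correct under controlled color statistics, not
that the classifier transfers to arbitrary real imagery.

## Numerical choices and degenerate inputs

Pixel coordinates are 1-based, x rightwards (columns), y downwards (rows).
Circle interiors are pixels strictly closer than the radius. Zoom uses
bilinear resampling for images and nearest-neighbour for masks. The
difference image `(a - b)/2 + 128` is rounded half-to-even, then clipped.
NIPALS iterates to a relative score tolerance of 1e-10 (500-iteration cap,
error on non-convergence, naming the component). Scaling refuses constant
columns by name. The opening's even-sized element is anchored at offsets
{0..9}²; opening is origin-invariant, so the result matches any other
anchoring convention. Box sums are exact integer cumulative sums, making
anti-extensivity and idempotence exact rather than approximate.

## Problem sizes used by the test suite

Unit tests run on 432 x 324 scenes; the end-to-end segmentation suite uses
twenty 864 x 648 scenes with the SOM trained on six of them (~4 x 10^5
median-RGB features, 30 updates per vector); regression tests use the full
21-chamber x 8-timepoint series (168 rows). These sizes were chosen so the
whole suite completes in a few minutes while every stage still runs at
study-like configuration (161 prototypes, stride-2 grids, 10 x 10 opening,
leave-one-chamber-out CV).
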