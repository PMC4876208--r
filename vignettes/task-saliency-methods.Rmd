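---
title: "Task-driven saliency: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-driven saliency: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TaskSaliency)
```

## The problem

In a visual-search task an observer's fixations are driven by three
competing pulls: the bottom-up conspicuity of the stimulus, the location of
the searched target, and the habitual bias toward the image center.
TaskSaliency models a per-pixel probability of fixation as a *linear*
combination of features expressing exactly these three pulls, learns the
combination weights from recorded gaze with a max-margin classifier, and
evaluates the result as a detector of held-out fixations. Linearity is a
deliberate modeling assumption: the weights of standardized features are
directly comparable effect sizes, so the fitted model doubles as an analysis
of what guided attention in a given study.

## Coordinate conventions and the canonical frame

Every computation happens at a fixed 200 x 200 frame. Images of any size
are resampled bilinearly; gaze coordinates are scaled by `(200/width,
200/height)` and floored to pixel indices; bounding boxes are scaled the
same way and re-expanded to at least 1 x 1 if scaling collapsed them.
Coordinates are 0-based with `x` the column and `y` the row; boxes are
half-open `[xmin, xmax) x [ymin, ymax)`. Annotations in the 1-based
inclusive Pascal-VOC XML dialect are converted on read (`xmin' = xmin - 1`,
`xmax' = xmax`). Working at one fixed resolution keeps every map, sample
count and statistic comparable across images regardless of native size;
original-resolution analysis is deliberately unsupported. Gaze samples are
ingested as fixation points as-is — no velocity-based event detection is
applied, so whatever filtering the recording software did (or did not do)
is inherited.

## Feature maps

**Bottom-up conspicuity.** The color, intensity and orientation channels
follow the classic center-surround architecture, re-dimensioned for a
200 x 200 frame:

* a 7-level Gaussian pyramid (levels 0–6; sizes 200, 100, 50, 25, 13, 7, 4),
  built with a separable 5-tap binomial filter and decimation;
* across-scale differences `|center − surround↑|` with center scales
  c ∈ {2, 3} and surround s = c + δ, δ ∈ {2, 3}. Four pairs per
  sub-channel; the pyramid is 7 levels deep precisely so that the deepest
  pair (3, 6) exists. Intensity uses `I = (r+g+b)/3`; color uses the
  double-opponent red–green and blue–yellow differences (negative lobes
  clipped at zero); orientation uses quadrature Gabor energy at 0°, 45°,
  90° and 135°;
* each intermediate map passes through the peak-promotion operator: after
  normalization to [0, 1] the map is scaled by `(1 − m̄)²`, where `m̄` is
  the mean of its local maxima other than the global one (3 x 3
  neighborhoods, maxima below 0.05 ignored). Maps with one dominant peak
  survive; maps speckled with comparable peaks are suppressed;
* normalized maps are upsampled to 200 x 200, summed per channel, and the
  channel is max-normalized to [0, 1]. A channel with no contrast anywhere
  (dynamic range at numerical-noise level, below 1e-9) is returned as the
  all-zero map rather than normalized noise.

One structural choice differs from the classic recipe: Gabor energy is
computed once at full resolution per orientation (wavelength 7 px, isotropic
envelope σ = 0.56 λ ≈ 3.9 px, zero-DC kernels, quadrature pair), and the
*energy map* is then pyramided. Filtering each pyramid level directly is
impossible at this frame size — the 21 x 21 kernel is larger than the 7 x 7
and 4 x 4 levels — and filtering at full resolution before multi-scale
differencing preserves the orientation selectivity the channel exists for.
All constants are exposed via `conspicuityConfig()`.

**Target location.** Inside a box the value is the distance from the pixel
center to the box center divided by the box half-diagonal (minimum across
covering boxes, most-target-like); outside all boxes it is zero. This
literal encoding is *small* at the box center and *zero* outside, which
makes the feature a ring-shaped detector of "inside a box, away from its
center". An inverted encoding (`1 − distance` inside, 0 outside), peaked at
the box center, is provided as an option (`invertedTarget = TRUE`); the
default stays literal. Both are implemented because a positive weight on
the literal encoding and a positive weight on the inverted one describe
different attention patterns, and the package takes no position on which a
given dataset exhibits — the learned weights decide.

**Center bias.** Distance from each pixel center to the frame center,
normalized so the corner pixels are exactly 1. The map is a constant of the
frame, computed once and cached; a *negative* learned weight on it means
"saliency decreases with eccentricity", i.e. classic center bias.

## Ground truth, sampling and learning

A fixation map is a sum of isotropic Gaussians (full support, evaluated
exactly via separable kernel products) centered at the gaze points, then
max-normalized; the default σ = 10 px corresponds to roughly one degree of
visual angle at a typical 65 cm desktop viewing distance and matches common
eye-tracker calibration accuracy. σ is a free parameter everywhere it
appears.

Per image, 20 training positives are drawn uniformly without replacement
from the top 20% of map values and 20 negatives from the bottom 70%
(quantile thresholds over all 40,000 pixels; ties at a threshold belong to
the stratum; a pixel never serves as both). The 1:1 class balance is
maintained by construction. Features are standardized with statistics
estimated on the training fold only and reused unchanged on the test fold —
the only leakage-free reading of train/test standardization. A feature that
is constant across the sampled pixels (e.g. the target feature in a fold of
target-absent images) carries no information for that fit; it is dropped
with a warning and recorded with weight 0 rather than aborting the fold.

The classifier is a soft-margin linear SVM (`e1071::svm`, C-classification,
cost C = 1, tolerance 1e-6). The weight vector is recovered from the
support-vector expansion and sign-oriented so that positive scores favor
the salient class; given identical inputs the optimizer is deterministic,
and every source of randomness in the pipeline (sampling, fold assignment,
generation) is derived from one master seed by hashing stage-specific keys,
so a whole cross-validation reruns bit-identically.

Cross-validation partitions images uniformly at random into k folds,
stratified by category so each fold sees every category — plain random
partitioning can leave a small category absent from a fold, which would
make per-category evaluation undefined. Per fold, one model per category is
trained on that category's training images.

## Evaluation

Predicted maps are scored against *fixated pixels* (pixels holding at least
one gaze point) — not against thresholded human maps, which would introduce
a second smoothing parameter. The AUC is computed in the rank
(Mann–Whitney) form so tied predicted values contribute 1/2; this equals
the trapezoidal area under the threshold-swept ROC, and both are exposed.
Per-category tables report mean and *population* standard deviation.
Inter-observer consistency scores, for each subject, the pooled smoothed
map of all other subjects against that subject's fixated pixels, averaging
over subjects within an image before averaging images within a
category-by-target-present group. No shuffled-AUC correction is applied;
the center-bias feature makes the bias explicit in the model instead.

Entropy of a (non-zero) saliency map is computed by normalizing the map to
a probability distribution over its 40,000 pixels and taking base-2 Shannon
entropy with `0 log 0 = 0`; the uniform map attains log2(40000) ≈ 15.29
bits. The plausible alternative — a histogram over gray levels — measures
contrast rather than spatial concentration, so the distribution-over-pixels
definition is fixed and not configurable. Center-bias fractions use, for
an area fraction f, the concentric axis-aligned rectangle of the frame's
aspect ratio scaled by √f (area exactly f); a gaze point counts as inside
when its pixel's center lies inside the region.

## What the synthetic generator emulates — and what it does not

The generator exists so every stage is testable with known ground truth.
Defaults mirror a desk-scale search study: 8 categories, 11 subjects, ~59%
target-present stimuli, 1–4 non-overlapping target rectangles of 20–60 px
per target-present scene, and per-subject gaze drawn i.i.d. from a mixture
of a target-centered Gaussian (weight 0.6, σ = 8 px), a frame-center
Gaussian (0.3, σ = 30 px) and a uniform component (0.1) — gaze counts of a
few tens of samples per subject per image. On scenes without boxes the
target weight is re-normalized onto the center/uniform components.
Distractor shapes reuse the palette colors of *other* categories, so
bottom-up color contrast is informative about "some object" but not about
"the target": the target-location feature has to earn its weight.

What this does **not** emulate: photorealistic scene statistics, saccade
dynamics and temporal ordering, subject idiosyncrasies (all simulated
subjects share one mixture), oculomotor and calibration noise, and
photographer's bias (box positions are uniform; the residual center bias in
simulated gaze comes only from the explicit center component and from
boxes being constrained inside the frame). Tests passing on this generator
therefore demonstrate that the pipeline recovers *planted* structure — they
do not certify performance numbers on human data, where feature weights and
AUC levels will differ.

## Numerical choices and degenerate inputs

* All-zero maps stay all-zero under max-normalization; a constant predicted
  score map min-max normalizes to the all-zero map by convention.
* `mapEntropy`, `centerFractionStats`, `targetHitStats` and sampling reject
  empty/all-zero inputs with contract errors instead of returning NaN.
* PNG saliency export quantizes as `floor(255 v + 0.5)` (round half away
  from zero); the float-CSV mode writes 17 significant digits and
  round-trips bit-exactly.
* Out-of-range gaze rows are reported with their row numbers and never
  clamped silently.
* Boxes collapsed by rescaling are expanded to 1 x 1; target boxes that
  cannot be placed without overlap after 1000 attempts abort generation.

## Study sizes used by the test suite

The suite exercises the pipeline at sizes chosen to make the statistical
checks decisive while keeping a full run comfortable on a laptop: weight
recovery uses 10 independently seeded studies of 8 categories x 10 images
with 5 subjects x 50 gaze points per image for each mixture condition
(target-dominated and center-dominated); the ablation comparison (full
model vs. model without the target feature) uses five seeded studies of the
same size under 5-fold cross-validation; inter-observer checks use two
10-image studies. The sampling-stage count check uses a 160-image study,
where 20 + 20 samples per map yield exactly 3200 positives and 3200
negatives.

## Known limitations

* The bottom-up channels are a re-dimensioned classic recipe, not a tuned
  reimplementation; absolute conspicuity values should not be compared
  against other saliency packages.
* One linear model per category assumes homogeneous strategy within a
  category and cannot express interactions between features.
* The target feature requires annotated boxes at prediction time: this is a
  model of *where people look given the task and the target locations*, not
  a target detector.
* IO consistency needs at least two subjects per image; single-subject
  images are skipped with a warning.
* With very small folds the per-category training set can lack
  target-present images; the target feature is then dropped (weight 0) for
  that fold, which slightly biases that fold's weight report toward the
  remaining features.
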