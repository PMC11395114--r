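---
title: "From well images to a Healthy Aging Index: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From well images to a Healthy Aging Index: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormaging)
```

## The problem

Lifespan assays in *C. elegans* increasingly place one worm per well of a
384-well plate and image each well daily. Two questions follow from such
data: is a given worm *elderly* (past the age at which only a small
fraction of its cohort remains alive), and what is its *biological* age —
the age its appearance suggests, as opposed to the calendar age we know
from the plate log? The gap between the two, summarized here as the
Healthy Aging Index (HAI), is what lets an imaging assay say that a
stressed cohort is "aging faster" than controls without waiting for the
survival curves to separate.

`wormaging` implements the full chain: synthetic data generation,
image preprocessing, segmentation (classical and learned), centerline
geometry, worm straightening, a residual convolutional network (WormCNN)
for elderly classification and age regression, evaluation metrics, and
survival-based age thresholds.

## Image model and preprocessing

Input images are single-worm brightfield well scans: a dark worm on a
brighter, noisy background. Preprocessing is a fixed three-step chain:

1. **Median denoising** (default 3x3, reflected borders) removes shot
   noise while preserving the worm's edges.
2. **Histogram equalization** uses the standard cumulative-histogram
   remap `round((cdf(v) - cdf_min) / (n - cdf_min) * 255)`; it is
   monotone, so pixel ordering is preserved.
3. **8-bit conversion** channel-averages multichannel input and rescales
   min-max to `[0, 255]`; the degenerate constant image maps to 0 by
   convention.

One consequence of equalization deserves emphasis: it maps intensities to
quantiles. For a small worm (a few percent of pixels) the equalized image
puts the worm near 0 and spreads the background almost uniformly over the
rest of the range, so *any* fixed threshold on the equalized image
selects a fixed fraction of pixels rather than the worm. The classical
segmentation path therefore thresholds the *denoised* image, where the
worm/background intensity gap is physical, while the equalized image is
used as the intensity source for straightened strips. If your raw images
put the worm near half the field of view the threshold may be applied
after equalization as well; both orders are reachable through the API.

## Segmentation

Two routes produce the binary worm mask:

* **Classical**: inverted thresholding (`255` where `I < t`, strict
  inequality, default `t = 128`), then morphological closing followed by
  opening with a 3x3 square structuring element, then filling of interior
  holes. Morphology uses the plain set-theoretic convention (pixels
  outside the image are background); the test suite checks it against a
  brute-force oracle on all 512 3x3 neighbourhoods and random grids.
  Hole filling matters because bright gut speckles in aged worms fall on
  the background side of the inverted threshold.
* **U-Net**: an encoder-decoder with skip connections — per level two
  3x3 convolution + batch-norm + ReLU blocks, 2x2 max pooling down,
  nearest-neighbour upsampling with a channel-reducing convolution and
  skip concatenation up, and a 1x1 convolution with sigmoid pixel output.
  Channels double per level. Training minimizes per-pixel binary
  cross-entropy with Adam. Input sides must be divisible by `2^depth`;
  other sizes are rejected with the suggestion to pad.

All network layers (convolution via im2col and BLAS matrix products,
batch normalization, pooling, Adam) are implemented in the package with
C++ kernels for the data movement; every forward operator is tested
against a direct-loop oracle and every backward pass against finite
differences. This keeps the pipeline runnable on a plain single CPU with
no deep-learning framework.

## Centerline geometry and straightening

The mask is thinned to a one-pixel skeleton (Zhang-Suen two-subiteration
thinning; the largest component is kept if the mask fragments). The
skeleton is ordered endpoint-to-endpoint after pruning side branches
shorter than `prune` pixels (default 5); only the shortest branch is
removed per pass so genuine worm arms ending near a junction are
protected. The start endpoint is canonical (smallest x, ties by smallest
y), making head/tail assignment deterministic but *not* biological —
pharynx detection is out of scope.

Key points are taken every `interval` path pixels (default 10, endpoints
always included) and the global orientation comes from an ordinary
least-squares fit of y on x, with `theta = atan(slope)`. Vertical worms
fall back to a `theta = pi/2` convention. The fit's RMS residual is
reported so callers can flag U-shaped worms, for which a single line is a
poor summary; the fit is still returned. Because the regression is of y
on x, exact rotation equivariance holds only in the small-residual limit;
the tests check a 2-degree tolerance on near-straight worms.

Straightening samples, at every path pixel, a perpendicular intensity
profile of length `2*half_width + 1` (default 31) by bilinear
interpolation. The default perpendicular direction is the *local* path
tangent (central differences over a +-3 px stencil, which smooths
single-pixel thinning kinks); a `"global"` mode that rotates every
segment by the single global angle is kept behind a flag for fidelity
experiments, since a whole-worm rotation is what a literal reading of the
rotation equations suggests — it degrades visibly on curved worms.
Profiles leaving the image are padded with the border-median background
and flagged. The profile stack is then bilinearly resized to the
canonical 600x30 strip (long axis = body position), the unit consumed by
WormCNN.

## WormCNN

The age network is deliberately small: a 3x3 convolution stem with 32
filters (padding preserves spatial dims), batch norm and ReLU; a stack of
identity-shortcut residual blocks
`ReLU(BN(Conv(ReLU(BN(Conv(x))))) + x)` at constant width (identity
shortcuts force equal channel counts — there is no projection path);
global average pooling; a 64-unit fully connected layer with ReLU; and a
1-unit head — sigmoid for elderly classification, linear for age
regression. Defaults: 3 residual blocks, 64 training epochs, Adam at
1e-3, inputs resized to 600x30 and scaled to `[0, 1]`.

Choices the architecture description leaves open, decided here once:

* The head is `Dense(64) -> ReLU -> Dense(1) -> sigmoid/linear`.
* Regression uses mean squared error on internally standardized ages
  (the model stores the centering and scale and de-standardizes its
  predictions), which makes the learning rate insensitive to the age
  range.
* The train/validation split is 80/20, stratified by label
  (classification) or age quartile (regression), seeded.
* Batch normalization uses batch statistics during training and running
  statistics at inference, so predictions are deterministic and
  independent of batch composition.

## Survival analysis and the HAI

Survival curves use the Kaplan-Meier product-limit estimator (via the
`survival` package); with no censoring this reduces to the daily
fraction-alive recount, and censoring is supported even though a plate
protocol that simply stops imaging dead worms produces none. The
*elderly threshold* is the first observed day at which survival is at or
below 20% (the fraction is a parameter), and a worm observation is
elderly when its age is at or beyond the threshold — the boundary day is
inclusive, a choice this package fixes deliberately.

The HAI report carries, per observation, the predicted biological age
(`hai`), the chronological age, and their difference (`deviation`).
The literature uses "HAI" both for the prediction itself and for its
deviation from chronological age, and group comparisons are sometimes
phrased with lower-is-worse, sometimes higher-is-older semantics; the
report therefore exposes both columns and leaves the group-level
contrast to the analyst. Under an unbiased age regressor the mean
deviation of a healthy cohort is near zero, and an accelerated-aging
cohort shows a positive mean deviation at matched chronological ages.

Whether elderly labels should be assigned per image (age at acquisition
vs threshold, the default here) or per worm (final lifespan vs
threshold) is genuinely ambiguous in the assay description; per-image
labeling is the default because it matches how strips are consumed at
training time, and the per-worm variant is a one-line relabeling of the
manifest.

## The synthetic cohort generator

No deposited image set accompanies the assay this package implements, so
the generator is a first-class module, not a test fixture. It emulates:

* **Geometry**: a single worm per well as a tube of age-dependent width
  along a smooth curve (straight axis plus two low-frequency sinusoids
  whose amplitude shrinks with age — old worms straighten and move
  less).
* **Intensity**: dark body (60) on a bright background (200) with
  Gaussian noise (sd 8), forced by the inverted-threshold convention.
* **Texture**: bright speckles inside the body whose density rises with
  age — a purely label-correlated stand-in for age-associated gut
  autofluorescence, with no biochemical claim.
* **Demography**: integer lifespans from a discretized Gompertz law
  (shape 0.3/day, baseline hazard 0.012/day; median near 10 days with a
  tail to ~20, the familiar shape of wild-type lifespan curves at
  20-25 °C), daily imaging until death, death-day imaging included and
  later days excluded.

The default aging law is width `6 + 0.5 * age` px (sd 0.3), curvature
amplitude `max(2, 14 - 0.5 * age)` px, speckle density
`0.02 + 0.012 * age`. An `accel` factor evaluates the phenotype at
`accel * age`, emulating stress-accelerated aging (the glycation-stress
comparison uses 1.6). These are engineering choices: the source assay
never characterizes its image statistics (contrast, SNR), so the
defaults were fixed once at values a microscopist would call plausible
and are not tuned against test outcomes.

What the generator does *not* emulate — and therefore what passing tests
do not establish about real data: multi-worm or touching-worm wells,
illumination gradients and vignetting, focus drift, coiled or
self-overlapping postures, debris, and the real (unknown) mapping from
age to appearance. Results on synthetic cohorts are property checks of
the *pipeline*, not reproductions of the assay's published performance
numbers, which belong to the authors' unreleased data.

## Problem sizes and numerical choices

Desk-scale defaults keep a full run on one CPU core in minutes: 64x64
canvases, depth-2/8-channel U-Nets trained on 16 images for 30 epochs
for the segmentation checks; a 200-worm cohort (about 2,000 images, of
which a seeded 1,000 are straightened), strips resized to 150x16, an
8-filter 2-block WormCNN trained for 8 epochs at learning rate 2e-3 for
the aging checks; 48-worm cohorts and a 4-filter 1-block regressor for
the HAI contrast. The canonical 600x30 strip size, 32-filter stem,
3-block depth and 64-epoch schedule remain the package defaults for real
use.

Other numerical decisions: thresholding uses a strict `<`; probability
masks binarize at 0.5 (the description of the learned segmenter is
silent on the cutoff); metric percentages round half-to-even at the
printed precision; metrics with zero denominators are returned as `NA`
and flagged rather than coerced to 0; ROC ties are grouped into a single
threshold step, making the trapezoid AUC equal to the tie-corrected
Mann-Whitney statistic; the degenerate min==max image rescales to 0;
Adam uses (0.9, 0.999, 1e-8); batch-norm epsilon is 1e-5.

## Known limitations

* Coiled worms (self-overlapping masks) are rejected at path ordering,
  not resolved; in cohort runs such frames are dropped and counted.
* The linear global-orientation fit cannot represent U-shaped worms;
  they are flagged via the fit residual, but the strip is still built
  from local tangents, which handles them in practice.
* Head/tail orientation is deterministic, not biological.
* The learned segmenter is trained here on synthetic ground truth;
  transferring it to real plates requires annotated masks.
* CPU training at full 600x30 resolution with the default architecture
  is possible but slow; the reduced input sizes above are the intended
  desk-scale operating point.
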