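---
title: "Methods: rice canopy phenotyping from multispectral plot imagery"
author: "ricecanopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rice canopy phenotyping from multispectral plot imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and data model

`ricecanopy` characterizes rice plot yield from five-band UAV reflectance
imagery (blue 450, green 560, red 650, red-edge 730, NIR 840 nm). The sample
unit is the *subplot tile*: each plot is an 8 x 5 lattice of 40 subplots,
and a field of 59 plots yields 2360 tiles. Two data sources feed the
package:

1. **The embedded field table** (`load_field_records()`): destructive
   5-plant samples per plot (fresh weight, oven-dry weight, water
   percentage, SPAD chlorophyll reading, plant height) at the vegetative
   stage, 59 plots. Weights are grams per 0.2 m2 sampling unit (5 plants
   per linear meter). Water content is `100 (fresh - dry) / fresh`; the
   package audits all 59 printed percentages against the weight columns
   (all agree within the 0.05 one-decimal rounding bound).
2. **Synthetic scenes** (`generate_scene()`): seeded multispectral fields
   with known canopy masks and latent traits, used to validate every
   downstream stage without proprietary imagery.

Harvest-stage weights are not embedded (no per-plot harvest numbers are
available); `biomass_gain_rate()` and `yield_per_area()` therefore take the
harvest weight, interval and sampling area as explicit arguments. The
headline yield figures reported for this field (about 10,253 kg/ha) cannot
be reconciled with the 0.2 m2 sampling unit and any tabulated weight — the
weight/area basis behind them is unstated — so the package computes yield
per area from user-supplied inputs and makes no claim to reproduce those
figures. Likewise the vegetative-to-harvest interval in days is never
stated and must be supplied.

## The synthetic scene generator

The generator emulates the study conditions, not radiative transfer:

* **Layout** — 59 plots x 40 subplots of 32 x 32 px at 2.5 cm/px, 8 plots
  per row, 8 px soil paths between plots.
* **Latent traits** — per-plot dry biomass ~ U(200, 400) g, SPAD ~
  U(30.58, 44.76), water content ~ U(64, 75) % (the spans of the embedded
  field table); wet biomass is derived as `dry / (1 - wc/100)`.
* **Canopy geometry** — one plant per subplot: a main elliptical crown plus
  two jittered tiller lobes, with total footprint mapped linearly from dry
  biomass to a canopy cover fraction in [0.35, 0.85]. The painted footprint
  *is* the truth mask (hard class boundaries, no mixed pixels).
* **Spectra** — soil means (0.10, 0.14, 0.18, 0.22, 0.26) with
  low-frequency texture (amplitude 0.02) so segmentation is not a constant
  threshold; canopy means (0.05, 0.10, 0.05, 0.35, 0.55) shifted affinely
  by SPAD: +0.012/unit in NIR, +0.008 in red-edge, -0.002 in red. The
  slopes put masked canopy NDVI in roughly 0.75-0.90 across the SPAD range
  while whole-plot means span ~0.3-0.8 as cover varies, against soil NDVI
  near 0.16 — values chosen once to sit in the typical vegetation range
  and to keep the trait-to-index link monotone (Spearman >= 0.8 between
  SPAD and masked plot NDVI at noise 0.02).
* **Noise** — i.i.d. Gaussian per band and pixel, sd 0.02 (reflectance
  units) by default, then clipping to [0, 1]. One global seeded stream.

What the generator does **not** emulate: mixed boundary pixels, shadows,
BRDF/sun-angle effects, within-plot trait gradients, registration error
between bands, or genotype-specific spectra (genotype labels are
placeholders). Passing the recovery benchmarks therefore demonstrates the
pipeline's internal consistency — segmentation finds the painted canopy,
the indices transmit the latent trait, the models recover it — not
field-level accuracy on real imagery, whose headline metrics are not
reproducible without the original (unpublished) data.

## Geometry

Pixel-to-ground orthorectification uses the pitch-corrected scale model

$$X = (x - c_x)\,\frac{H}{h} - (y - c_y)\tan(\phi)\,\frac{H}{h} + X_0,
\qquad
Y = (y - c_y)\,\frac{H}{h}\cos(\phi) + Y_0,$$

implemented exactly in this stated form (the asymmetric small-pitch
treatment of the two axes is deliberate and kept as-is). The map is affine,
so `distort_frame()` (its exact inverse) and `orthorectify_raster()`
(inverse mapping onto an integer ground grid + bilinear resampling;
nearest-neighbour for masks) round-trip to sub-pixel accuracy. Pixel
convention throughout: 0-based, x = column, y = row, centers at integers,
rectangles half-open. Channel registration fits a 6-parameter affine per
band to control-point pairs by least squares — enough for the
translation/rotation/scale residuals of marker-aligned channels — and
reports the residual RMS.

## GFKuts segmentation

Three stages produce the binary canopy mask:

1. **K-means** (K = 3 by default: canopy / soil / mixed). Lloyd iterations
   with k-means++ seeding, 5 restarts, lowest within-cluster sum of squares
   kept; the objective trace is exposed and non-increasing. Clusters are
   ordered by mean NDVI: top cluster becomes sure-foreground, bottom
   sure-background, the rest unknown. If no cluster reaches NDVI 0.3 the
   scene is declared canopy-free rather than forcing a foreground.
2. **GrabCut** on the unknown pixels: per-region Gaussian-mixture color
   models (up to 5 components, fit on a 3000-pixel subsample), region
   terms = negative log-likelihoods, boundary terms
   $\lambda \exp(-\beta\|z_i-z_j\|^2)/d_{ij}$ on the 8-neighborhood with
   the canonical $\beta = 1/(2\,\overline{\|z_i-z_j\|^2})$ and
   $\lambda = 50$; solved as a min s-t cut. Because log-likelihood costs
   can be negative, both terminal capacities are shifted by their per-node
   minimum (the cut depends only on the difference). Sure pixels never
   flip; the energy is tracked per iteration and the loop reverts and
   stops if a model refit would increase it, so the reported trace is
   non-increasing by construction.
3. **Guided filter** with the NIR band as guidance (highest canopy
   contrast), radius 4 px, epsilon 1e-3, followed by a 0.5 threshold. The
   implementation is the standard local-linear-model filter; note its
   large-epsilon limit is the box mean applied twice (the window average
   of the per-window means), which the tests assert in that form.

K, lambda, epsilon, the window radius, the GMM size and the guidance band
have no canonical values for this method; the defaults above are the
package's own choices, exposed in `gfkuts_params()`, with no claim of matching any prior tuning of the method. On large fields the mask is
computed plot-by-plot (each plot rectangle expanded by half the soil gap),
which keeps each graph-cut problem at ~40k pixels.

## Vegetation indices

Ten per-pixel indices (DVI, NDVI, GNDVI, SAVI, MSAVI, CTVI, SR, TVI, EVI,
ARVI) in their standard closed forms. ARVI circulates in two variants that
differ in the roles of the red and blue bands; the standard form
`RB = RED - gamma (BLUE - RED)` is the default and the red/blue-swapped
variant is additionally exposed via
`vi_params(arvi_literal = TRUE)` for auditability. EVI constants default to
the canonical G = 2.5, C1 = 6, C2 = 7.5, L = 1; SAVI soil factor L = 0.5;
ARVI gamma = 1. Denominators below `eps_div` (1e-10) yield flagged NAs
rather than huge values. Mask-weighted statistics use Tukey's 1.5 IQR box
plot rule; soft masks weight the mean and the empirical quantile function.
Box-plot statistics default to per-pixel values within a plot; per-subplot
means are available by aggregating the feature matrix.

## Feature sets, split and models

Feature sets per subplot tile: FS1 = ten mask-weighted VI means +
genotype ID; FS2 = five whole-tile channel means + mean segmentation
value + genotype ID; FS3 = VI means + channel means + height; FS4 = mean
segmentation value + height. Genotype ID enters as an ordinal integer code
by default (a one-hot option exists); it and height are treated as
predictors. Labels are wet biomass, dry biomass and SPAD replicated from
the tile's plot record.

The split reserves 8 random subplots per plot (472 of 2360) as the
held-out test set; the remaining 1888 form the cross-validation pool, from
which 5 independent random 70/30 train/validation partitions are drawn
(disjoint fifths cannot give a 70/30 split, so the folds are resamples).

Five model families: regression tree (rpart), bagged-tree ensemble
(ranger), Gaussian process regression (own implementation: Cholesky solve,
RBF or Matern-5/2 kernel, lengthscale and noise hyperparameters — needed
for exact kernel control and the zero-noise interpolation property),
epsilon-SVR with RBF kernel (e1071), and a single-hidden-layer network
(nnet, width 4-128, weight decay). Features are z-scored on the training
data inside each fit; labels stay in natural units (the network scales its
target internally).

Hyperparameters are tuned by Bayesian optimization: Latin-hypercube
initial design, Gaussian-process surrogate on the unit cube over the log
mean-validation-MSE, expected-improvement acquisition over 256 random
candidates per step. Budgets default to per-family counts reflecting each family's training
cost (GPR 5, NNR 300, SVMR 600, ER 800, TR 900 evaluations); the test-suite and
acceptance runs use the GPR family (budget 5) at full field scale and
reduced budgets (3-8 evaluations) for the slower families on small scenes,
which is the package's desk scale for validating the machinery. Search
ranges are package choices (none are published): tree depth 1-30 and leaf
size 1-50; 50-500 trees; GP lengthscale 0.1-30 and noise 1e-6-1 (log);
SVR C 0.01-1000, gamma 1e-4-10, epsilon 1e-3-1 (log); network width 4-128
and decay 1e-5-1 (log).

Evaluation on the held-out rows: R2 centered on the test mean, MAE, RMSE.
Reference scores for the original field imagery are out of reach (that
imagery is not public), so model validation rests on identities (perfect
and mean predictors, RMSE >= MAE), no-signal controls, and latent-trait
recovery on synthetic scenes (GPR on FS1 reaches R2 > 0.99 for SPAD at
field scale, the desk-scale stand-in for best-case field performance).

## Numerical choices and degenerate inputs

* Division guards: index denominators below 1e-10 give NA; empty-mask plot
  statistics return an explicit empty result, never silent zeros.
* GP factorization: jitter grows from 1e-10 by decades until the kernel
  matrix factors; zero-variance labels are refused.
* K-means with empty clusters keeps the previous center; cluster NDVI
  ordering ignores empty clusters.
* MSAVI's discriminant is clamped at 0 before the square root (it is
  non-negative for reflectances in [0, 1] anyway); TVI is NA where
  NDVI < -0.5.
* Correlation matrices flag constant columns as undefined (NA), enforce
  bit-exact symmetry and a unit diagonal.
* All randomness flows from explicit seeds; the pipeline driver derives
  one stream per stage from the root seed and records them in the run
  manifest together with md5 checksums of every output file.

## Known limitations

* The camera model has no lens-distortion terms and the package does not
  stitch orthomosaics from overlapping frames; inputs are assumed to be
  single georeferenced scenes (real or synthetic).
* Soft (probabilistic) masks are supported in the statistics layer, but
  GFKuts itself emits binary masks after thresholding.
* Genotype is an ordinal code by default; with many unordered genotypes a
  one-hot encoding (provided) or target encoding may serve tree models
  better.
* The GP scales cubically; it is comfortable at the 1888-row study scale
  but not far beyond.
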