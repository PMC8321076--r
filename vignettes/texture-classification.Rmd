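---
title: "Texture features and classifier ranking for melanoma/nevus patches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture features and classifier ranking for melanoma/nevus patches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermtex)
```

## The problem and the model

dermtex discriminates malignant melanoma from benign nevus in RGB skin
images using *local texture*, not whole-lesion morphology. The unit of
analysis is a small square patch ("keypoint"): 6×6 pixels by default,
sampled at random positions so the representation does not depend on
where the lesion sits in the frame. Each patch is summarised by 28
numbers:

* **First-order statistics** of the intensity histogram — mean,
  population variance, skewness and *excess* kurtosis (a normal
  distribution scores 0), plus min and max. These are computed on the
  unquantized grayscale values normalized to [0, 1], and again on each
  of the R, G, B channels (the colour information is what
  distinguishes this feature set from plain grayscale texture
  analysis).
* **Second-order (Haralick) statistics** of the gray-level
  co-occurrence matrix (GLCM): energy `sum p(i,j)^2`, entropy
  `-sum p log2 p` (bits), correlation of the row/column level indices,
  and contrast `sum (i-j)^2 p(i,j)`. The GLCM `p(i,j | d, theta)` is
  the normalized count of pixel pairs whose levels are `i` and `j` at
  displacement distance `d` and angle `theta`.

A zoo of twelve standard classifiers (SGD linear, three naive Bayes
variants, decision tree, extra trees, random forest, gradient
boosting, k-NN, linear SVC, RBF SVC, logistic regression) is trained
on the patch table and ranked by test-set AUC; the top five are
flagged. Melanoma is the positive class everywhere.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| patch size | 6 | px | the keypoint window; small enough to capture local texture, large enough for 30 horizontal pairs |
| patches/image | 10 | — | the sampling density of the study design |
| `L` (gray levels) | 8 | levels | a 6×6 patch has only 30 pairs per offset; 256 levels would make every GLCM a scatter of singletons. First-order features ignore `L` (they use unquantized values) |
| distances `d` | 1–5 | px | offset range of the co-occurrence geometry |
| angles | 0°, 45°, 90°, 135° | — | the four lattice directions; (Δx, Δy) offsets with y downward |
| train fraction | 0.75 | — | image-level split; all patches of an image stay on one side |
| grayscale weights | (0.299, 0.587, 0.114) | — | ITU-R BT.601 luma; configurable |

Per-(d, θ) features are averaged into one value per Haralick feature
(20 combinations on the default grid). Averaging, rather than
concatenating 20 × 4 columns, is the standard Haralick reduction and
matches a feature list that names each statistic once. On a 6×6 patch
every default combination is valid; combinations whose offset exceeds
the patch extent (possible with narrow ROIs or larger `d`) are skipped
and recorded, and only a patch with *no* valid combination raises an
error.

## The classifier zoo

Library defaults throughout, with two deliberate choices:

* **Standardization.** Margin- and distance-based learners (SGD,
  linear SVC, RBF SVC, k-NN, logistic) receive z-scored features,
  fitted on the training split only. Multinomial naive Bayes needs
  nonnegative inputs and receives min–max [0, 1] scaled features;
  Bernoulli naive Bayes binarizes the z-scores at 0 (above/below the
  training mean). Tree ensembles and Gaussian naive Bayes take raw
  features. Without scaling, margin learners are crippled by the
  heterogeneous feature ranges (contrast spans [0, 49], means span
  [0, 1]).
* **Scores.** AUC uses the melanoma-class probability where the
  learner provides one, otherwise the decision margin, sign-oriented
  on the training split so that larger always means more
  melanoma-like.

The 28 features are exactly collinear (the grayscale mean is the luma
combination of the channel means); the logistic fit therefore zeroes
aliased coefficients, the same convention `lm`/`glm` use when they
drop aliased columns.

## The synthetic generator

`generate_image()` emulates the *statistical* structure of dermoscopy
patch populations, not their appearance: no lesion borders, hair, or
ABCD morphology. The pipeline is

1. a Gaussian random field — white noise smoothed with a separable
   Gaussian kernel of scale `corr_length` (edge-renormalized), then
   standardized per image;
2. a monotone sinh–arcsinh transform `sinh((asinh(z) + ε) / δ)` whose
   (ε, δ) are solved once per parameter set by least squares so the
   transformed normal approaches the target skewness and excess
   kurtosis (heavy-tailed targets are reachable, exact attainment is
   not guaranteed and not required);
3. rescaling to the class mean/SD, clipping to [0, 1] (the clipped
   fraction is attached to the image), a per-channel multiplicative
   colour cast, and 8-bit quantization.

Colour casts are rescaled to unit BT.601 luma, so tilting the channel
balance never moves the grayscale mean off its target — without this,
a cast of a few percent would bias the pooled patch means by more
than their standard error.

The default classes use the observed class-conditional grayscale
moments (nevus mean 0.4514, SD 0.1434, skewness 0.1935, excess
kurtosis 3.0953; melanoma 0.4204, 0.1543, 0.2479, 3.6476). Those
means alone overlap far too much to support the discrimination the
full 28-feature joint distribution achieves on real dermoscopy data,
and that joint distribution is not observable from published summary
tables. The generator therefore adds two invented, documented
contrasts that carry the texture signal: correlation length 4 px for
nevi vs 1 px for melanomas (smoother vs more cluttered texture) and
mild, distinct colour casts (nevi warm brown, melanomas slightly
violet). Passing the end-to-end tests consequently shows that the
pipeline *detects the statistical structure it was given*; it says
nothing about classification accuracy on real lesions.

Under the default heavy-tailed classes roughly 0.5–1% of pixels clip
at the [0, 1] boundary, which shaves about 4% off the realized SD;
means stay on target to ~0.003. The moment-recovery tests reflect
this: exact recovery is asserted in an unclipped regime, the default
regime with a wider band.

## Numerical and degenerate-case policies

* Quantization maps `v` to `min(floor(v·L), L−1)`: monotone, and 1.0
  lands on the top level.
* A constant patch has variance 0; skewness and kurtosis are defined
  as 0 (not an error) so degenerate patches flow through. Its GLCM has
  `sigma_x·sigma_y = 0`; correlation is defined as 1 ("perfectly
  predictable neighbour"), energy 1, entropy 0, contrast 0.
* Entropy uses `0·log 0 = 0` and base-2 logs (bits).
* Metrics with zero denominators (e.g. precision with no positive
  calls) are `NA` markers, never silent zeros.
* The ROC sweep groups tied scores into one step; the trapezoidal
  area then equals the Mann–Whitney concordance probability (ties
  counted ½) to 1e−9, an identity the tests assert on random score
  vectors.
* The Mann–Whitney p-value is exact (enumeration) when
  `n1·n2 ≤ 200` without ties, else a tie-corrected normal
  approximation; an all-ties comparison degenerates to p = 1.
* Patch corners are sampled without replacement whenever the
  admissible region offers at least `n` positions; a region with
  fewer positions (e.g. an image exactly the patch size) falls back
  to replacement so the requested count is always honoured.
* Per-image and per-model seeds are derived from the master seed by a
  polynomial string hash of the image id / model name, so results are
  independent of processing order and every artifact is a pure
  function of the master seed.

## Design choices that were genuinely open

* **Keypoint sampling.** "Keypoints" could suggest a saliency
  detector, but none is specified for this strategy; uniform random
  sampling within the (caller-supplied) ROI is the stand-in, and the
  ROI mechanism lets a user plug in any lesion localization upstream.
* **Split unit.** Images, not patches, are randomized into train/test
  — sibling patches of one image are near-duplicates, and a
  patch-level split would leak them across the boundary. The
  anti-leakage tests verify id-disjointness across 100 seeds and that
  a label permutation (applied to both sides at patch level after the
  split) drives every model's AUC to 0.5 ± 0.05. Permuting *only*
  training labels does not produce chance AUC here: a noise-trained
  linear rule is still a random direction in feature space, and
  genuinely separable test classes project onto any direction with
  AUC well away from ½ — a property of permutation tests worth
  remembering when auditing pipelines on separable data.
* **Split allocation.** Largest-remainder rounding of per-class image
  counts keeps every class within one image of the global fraction
  while the total equals `round(fraction · n_images)`.
* **First-order scale.** Statistics are computed on [0, 1] normalized
  intensities (reported class means near 0.42–0.45 imply that scale,
  not 0–255).
* **Histogram normalization** divides by the total pixel count `N·M`;
  dividing by one image dimension alone cannot sum to 1.
* **Specificity** is `TN/(TN+FP)` (the standard definition matching
  "fraction of actual negatives called negative").

## Problem sizes used by the tests

The shipped tests run the full pipeline at 200 images/class (64×64 px,
4000 patches, twice for reproducibility), the permutation audit at 250
images/class (5000 patches), and moment recovery at 100 images/class
(1000 patches/class); oracle-equivalence checks use exhaustive
enumeration on patches up to 8×8 at `L ≤ 4` and 1000 random 36-pixel
patches. These sizes are the package's chosen study conditions for a
self-contained, deterministic test corpus.

## Known limitations

* The generator reproduces marginal moments, spatial correlation and
  colour balance — not lesion morphology, JPEG artifacts, vignetting,
  rulers/hair, or inter-patient variability. End-to-end AUCs on it are
  properties of the emulation, not clinical estimates.
* Skewness/kurtosis shaping is approximate by design, and [0, 1]
  clipping interacts with heavy tails (see above).
* Only the four named Haralick features are implemented; the other
  ten of Haralick's original set are out of scope.
* Hyperparameters are library defaults; no tuning, calibration or
  ensembling is provided.
* `d = 5` diagonal offsets on a 6×6 patch rest on a single pixel pair;
  they are kept (the offset grid is part of the design) but such GLCMs
  are extremely coarse — another reason feature values are averaged
  over the 20 combinations.
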