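---
title: "Evaluating saliency-map explanations of fundus-image classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating saliency-map explanations of fundus-image classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fundusXAI)
```

## The problem

Convolutional classifiers grade diabetic retinopathy (DR) from fundus
photographs on the five-level scale 0-4 (normal; mild, moderate and severe
non-proliferative DR; proliferative DR). Clinical grading is driven by
visible lesions — microaneurysms, hemorrhages, hard and soft exudates — so a
trustworthy grading model should attend to those lesions. Saliency
(attribution) maps make that attention inspectable, but a saliency map is
itself a measurement instrument that needs validation: does masking the
highlighted pixels actually change the prediction, and do the highlights
fall on annotated lesions?

`fundusXAI` packages that validation loop: attribution methods behind a
model-agnostic classifier contract, a perturbation-based faithfulness
protocol, dispersion and overlap metrics, and a controlled lesion-insertion
experiment. Because clinical images and trained hospital models cannot be
redistributed, the package also generates synthetic fundus scenes with exact
lesion masks and provides fixture classifiers with known closed-form
behaviour, so every metric can be verified against an independent oracle.

## The classifier contract

All methods see a model only through a `classifier_handle`:

* `predict_scores(image)` — real-valued class scores (logits);
* `predict_probs(image)` — probabilities (softmax of the scores unless the
  model defines them directly);
* optionally a gradient of a target-class score w.r.t. the input
  (capability `differentiable`);
* optionally convolutional feature maps, with their gradients on request
  (capability `exposes_feature_maps`).

Two conventions deserve justification because the choice is genuinely open:

* **Confidence is the softmax probability.** Perturbation curves plot a
  bounded quantity in \[0, 1\]; probabilities are that quantity.
* **Attributions target the class score, not the probability.** Gradients of
  a softmax probability entangle all classes; the standard completeness
  axioms (attributions summing to `f(x) - f(baseline)`) are stated for the
  score, and the linear-model oracle ("the gradient is exactly the weight
  vector") only holds at the score level.

The default CAM layer is the last convolutional stage of the wrapped
network; a handle may expose several stages by id. `disable_gradients()`
returns a copy of a handle without gradient access — ScoreCAM is verified to
run on such a handle, since it is a purely forward-pass method.

Inputs are `height x width x channels` arrays in \[0, 1\], 224 x 224 RGB by
default, with 0-based class indices matching the DR grades. Resizing and
intensity scaling live in the I/O layer (`load_image()`), never in the
handle.

## Attribution methods

Seven methods are implemented from first principles, each returning a
`saliency_map` with the signed per-channel attributions (`raw`) and a
nonnegative 2-D aggregate (`map2d`):

* **Gradient** — the raw input gradient.
* **SmoothGrad** — mean gradient over `sg_samples = 25` Gaussian-noised
  copies, noise sd `sg_sigma = 0.15` of the intensity span. Noise is *not*
  clipped to the valid range (clipping would bias the average near the
  domain boundary). With `sg_sigma = 0` the method short-circuits to the
  plain gradient, making the degenerate equivalence exact rather than
  floating-point-approximate.
* **Integrated Gradients** — midpoint-rule path integral from the baseline,
  `ig_steps = 32` by default. The midpoint rule was chosen over the
  trapezoid because it avoids evaluating the gradient exactly at the
  baseline (where ReLU activation patterns are degenerate) and has the same
  O(1/n) convergence.
* **SHAP (expected gradients)** — Monte-Carlo Shapley estimator sampling a
  baseline and a path position `a ~ U(0, 1)` per draw, `shap_samples = 64`.
  A superpixel-based Kernel SHAP variant was deliberately not used: fundus
  lesions are small and poorly delimited, which is exactly the regime where
  superpixel segmentation fails.
* **DeepLIFT (Rescale rule)** — backward multiplier propagation. Linear
  layers (dense, convolution, pooling, inference-mode normalization) use
  their bias-free transpose; ReLU uses the secant slope
  `(relu(x) - relu(b)) / (x - b)` when `|x - b| > 1e-7` and the local
  gradient otherwise. Summation-to-delta then holds to machine precision by
  construction. The RevealCancel rule is out of scope.
* **Grad-CAM++** — closed-form per-map weights
  `alpha = g^2 / (2 g^2 + sum(A) g^3)` with a `1e-8` stabilizer,
  `w_k = sum(alpha * relu(g))`, ReLU of the weighted activation sum,
  bilinear upsampling to the input grid.
* **ScoreCAM** — gradient-free: each activation map is min-max normalized,
  upsampled, used as a multiplicative image mask; weights are the softmax
  over maps of the target-score increase relative to the all-black image.
  Constant maps carry no spatial structure and contribute a zero map while
  keeping their softmax weight; an all-zero stack yields the zero map rather
  than an error.

**Baseline policy.** Reference-based methods (IG, SHAP, DeepLIFT) default to
the all-black image. For fundus photographs black is the natural "absence"
reference — the region outside the field of view is already black — and it
makes the three methods directly comparable.

**Channel aggregation.** `map2d` is the per-pixel sum of absolute raw
attributions over channels. Taking absolute values before summing keeps
negative evidence visible in the 2-D map; summing after would let opposing
channel attributions cancel.

## Quality metrics

* **Entropy.** The map is min-max normalized and then sum-normalized to a
  pixel distribution; `H = -sum p log2 p` in bits. Min-max values alone do
  not form a distribution, so the sum-normalization step is required for a
  well-defined entropy; base 2 is chosen because the resulting ceiling for a
  224 x 224 map, `log2(50176) ~ 15.615` bits, is the natural reference
  point: a uniform (completely unfocused) map attains it exactly, and any
  reported map entropy must sit below it.
* **Perturbation curves and AOPC.** All pixels are ranked by saliency (ties
  broken in stable row-major order, making curves fully deterministic) and
  cumulatively masked in 2 % increments (K = 50 steps), replacing masked
  pixels with black on all channels; the target-class confidence is recorded
  at each ratio. `AOPC = mean_k (f(x) - f(x^(k)))`. Masking with black
  mirrors the attribution baseline; the mask value is configurable. Pixel
  granularity (not patches) follows from ranking individual pixels.
* **Recall and Dice.** The normalized map is thresholded at its 0.9 quantile
  (linear-interpolation quantile; strictly-greater retention, so a constant
  map highlights nothing) and compared with the union of all lesion-class
  masks. Pooling classes reflects that any annotated lesion is a clinically
  valid attention target. Images with empty masks (grade 0) skip both
  metrics — they are reported as missing, not as zero, since zero would
  falsely signal "highlight missed the lesions" where there are no lesions.
* **Report layout.** `evaluate_batch()` / `run_pipeline()` emit one record
  per (image, method) and aggregate per (model, grade), averaging over the
  images of a grade and over methods. The two CAM methods are excluded from
  the aggregated quality tables by default (their perturbation curves are
  unstable at pixel granularity because the maps are piecewise-smooth
  upsamplings with massive ties); the exclusion list is configurable.

## The lesion-insertion trend experiment

Lesion patches are extracted from annotated (synthetic) donor images via
polygon rasterization (even-odd rule on pixel centres, 0-based (row, col)
coordinates), cropped with a margin and feathered with a finite Gaussian
kernel (radius 2 px), so the alpha mask is exactly 0 on the patch border and
1 deep inside. Sequences with controlled lesion counts — 14, 12, 10, 8, 6
microaneurysms and 13, 11, 9, 7, 5 hemorrhages — are alpha-composited onto a
lesion-free scene at seeded uniform-random non-overlapping positions inside
the field of view, avoiding the optic disc; outside the feather supports the
composed image equals the base exactly.

The original experiment was qualitative (inspecting ScoreCAM maps as counts
change). To make it testable the package adds a clearly-labelled
quantitative surrogate, `trend_overlap_score()`: the fraction of
sum-normalized saliency mass inside the union lesion mask dilated by 5 px
(the dilation absorbs the spatial blur a CAM map inherits from upsampling).
A uniform map scores `dilated-area / n`, which is the reference baseline;
the planted-detector fixture (whose single feature map responds to deviation
from the stored lesion-free base) must beat it at every count.

## Synthetic scenes and fixture models

Scenes are stylized, not photorealistic: a circular field of view with a
radial colour gradient and smooth seeded texture, a bright optic disc, dark
tapering vessel arcs, and hard-edged lesion discs/ellipses (microaneurysms
2-5 px radius, hemorrhages 4-10 px, both capped at 8 % of the scene side,
with radii shrinking under placement pressure so dense plans remain
placeable). Masks exactly cover rendered lesion supports, and generation is
a pure function of (spec, seed). Grades follow a documented count surrogate
of clinical grading: no lesions = 0, microaneurysms only = 1, both classes =
2-4 by hemorrhage count. What passing tests on these scenes demonstrate is
the *geometry and bookkeeping* of the pipeline — mask alignment, mass
placement, metric arithmetic — not clinical appearance; results on real
fundus photographs additionally depend on photographic noise, annotation
quality and model calibration, none of which the generator emulates.

Fixture classifiers:

* `region_fraction` — target-class probability equals the mean intensity in
  a planted region; the perturbation curve under the region-indicator
  saliency has an exact closed form, the AOPC oracle.
* `intensity_linear` — softmax over linear functionals; gradients equal the
  stored weights exactly, and IG/DeepLIFT/SHAP attributions have closed
  forms.
* `tiny_cnn` — conv(3x3, s2) / ReLU / conv(3x3, s2) / ReLU / global average
  pool / channelwise inference-mode normalization / dense, implemented on an
  in-package sequential engine with exact backprop and DeepLIFT multiplier
  propagation. Every layer type is in the DeepLIFT-supported set, which is
  why the architecture is fixed at two convolutional stages.
* `make_single_map_model` — one block-mean-luminance feature map with fixed
  class weights: both CAM methods provably collapse to (a positive multiple
  of) the upsampled activation map on it.

`train_tiny_cnn()` calibrates the normalization layer to the training-set
pooled-feature statistics and then fits the dense readout with per-sample
Adam (convolutional stages keep their seeded random weights — random-feature
training). The calibration matters: raw pooled features are so
ill-conditioned that first-order optimization stalls near chance, while the
standardized problem separates in a single epoch. Five epochs on 200 scenes
(healthy vs. lesion-bearing, 64 x 64) reach training accuracy 1.0
deterministically.

## Numerical choices and degenerate inputs

* Constant saliency maps: min-max normalization returns a constant 0.5 map
  flagged `degenerate`; sum-normalization of a zero map returns the uniform
  distribution, also flagged. Both choices keep downstream metrics defined
  while marking that the map carried no information.
* Quantile convention: R's type-7 (linear interpolation) quantile; on a
  10 x 10 map holding the distinct values 1..100 the 0.9 threshold retains
  exactly the 10 pixels valued 91..100.
* Perturbation tie-break: stable row-major order (radix sort), so curves on
  tied maps are reproducible across platforms.
* Bilinear upsampling uses the half-pixel-centre convention with clamped
  borders; the same routine serves CAM upsampling and image resizing.
* Seeds: every stochastic component (SmoothGrad, SHAP, scene generation,
  placement, training) takes an explicit seed and restores the caller's RNG
  state; two runs with one seed are bit-identical.

## Problem sizes

The shipped tests and the acceptance script run at the study's native
224 x 224 resolution for the scale-sensitive checks (entropy ceiling,
perturbation oracle, CAM cosine alignment, the two insertion sequences, and
a 25-scene x 5-method pipeline) and at 8-64 px for the per-pixel oracles
(finite differences over every input coordinate, brute-force polygon
rasterization), where exhaustive enumeration is the point. These sizes were
chosen so each oracle is exercised at full precision while the whole suite
stays comfortably runnable on a laptop CPU.

## Known limitations

* No adapter for serialized network checkpoints is included: the contract is
  designed so that wrapping a real model (e.g. through an external runtime)
  only requires implementing the three closure fields, but doing so is left
  to the user's environment.
* DeepLIFT supports the primitive-layer vocabulary of the fixture engine;
  handles built from other layer families report a capability error naming
  the limitation rather than silently falling back to gradients.
* The trend experiment's overlap score is a surrogate the package defines,
  not a literature-standard metric; conclusions drawn from it should be
  phrased in terms of "saliency mass on inserted lesions".
* Grad-CAM++/ScoreCAM quality depends on which convolutional stage is
  exposed; for unfamiliar architectures the default (last stage) should be
  checked against the alternatives.
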