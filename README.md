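# fundusXAI

Saliency-map evaluation for diabetic-retinopathy (DR) grading models.

DR classifiers assign fundus photographs to five grades (0 = normal through
4 = proliferative DR). Clinicians grade by lesions — microaneurysms,
hemorrhages, exudates — so an interpretable grading model should attend to
lesions, and that claim should be *measured*, not eyeballed. `fundusXAI` is
an R framework for exactly that measurement, aimed at researchers evaluating
the interpretability of image classifiers in ophthalmology (or any imaging
domain with pixel-level ground-truth annotations).

## What it computes

Given a classifier behind a small model-agnostic contract
(`classifier_handle`: class scores, probabilities, optional input gradients
and feature maps), the package provides:

* **Seven attribution methods**, implemented from first principles:
  Gradient, SmoothGrad, Integrated Gradients, expected-gradients SHAP,
  DeepLIFT (Rescale rule), Grad-CAM++ and ScoreCAM.
* **Faithfulness via perturbation curves**: pixels ranked by saliency are
  cumulatively masked in 2 % increments; the curve of target-class
  confidence `f(x^(k))` yields

  `AOPC = (1/K) Σ_{k=1..K} ( f(x) − f(x^(k)) )`, K = 50.

* **Dispersion via entropy**: the map is min-max normalized
  (`p_i = (I_i − min I) / (max I − min I)`), sum-normalized to a pixel
  distribution, and scored with `H = −Σ p_i log2 p_i` (bits; ceiling
  `log2(224·224) ≈ 15.615` for an unfocused map).
* **Lesion overlap**: the top decile of the normalized map (0.9-quantile
  threshold) is compared with the union lesion mask via
  `Recall = TP / (TP + FN)` and `Dice = 2|A∩B| / (|A| + |B|)`; images
  without lesions (grade 0) skip both by convention.
* **A lesion-insertion trend experiment**: annotated lesion patches are
  feathered and alpha-composited onto a lesion-free fundus in controlled
  counts (14, 12, 10, 8, 6 microaneurysms; 13, 11, 9, 7, 5 hemorrhages), and
  ScoreCAM attention is checked against the inserted-lesion masks.
* **Synthetic fixtures**: a seeded fundus-scene generator with exact lesion
  masks and grade labels, plus fixture classifiers with closed-form behavior
  (linear models, a planted-region model, a tiny CNN with exact backprop and
  DeepLIFT), so everything above is verifiable against independent oracles
  without clinical data.

## Worked example

```r
library(fundusXAI)

# a synthetic grade-2 scene with exact lesion masks
scene <- generate_fundus(fundus_scene_spec(size = 224, n_microaneurysm = 4,
                                           n_hemorrhage = 2, seed = 7))
sum(scene$masks$union)   # 514 lesion pixels
scene$grade              # 2

# an (untrained) fixture CNN and an Integrated-Gradients map
model <- make_tiny_cnn(input_spec(), seed = 1)
sal <- integrated_gradients(model, scene$image, scene$grade,
                            attribution_config(ig_steps = 32))
saliency_entropy(sal$map2d)                     # 14.912 bits

curve <- perturbation_curve(model, scene$image, sal$map2d, scene$grade)
aopc(curve)                                     # -0.0959

bin <- binarize_top_percentile(normalize_minmax(sal$map2d))
overlap_recall(bin, scene$masks$union)          # 0
overlap_dice(bin, scene$masks$union)            # 0
```

The numbers tell a coherent story for a random-feature model: its saliency
is dispersed (entropy 14.91 of the 15.61-bit ceiling), masking its
"important" pixels barely moves the prediction (AOPC ≈ −0.10), and its top
decile misses every lesion (Recall = Dice = 0). A faithful, lesion-aware
model scores low entropy, high AOPC and nonzero overlap — the planted
fixtures in the test suite demonstrate both extremes.

The trend experiment, with a detector that responds to inserted content:

```r
trend <- run_trend_analysis(detector, base, patch_pool,
                            counts = c(14, 12, 10, 8, 6), target = 2, seed = 1)
#   count overlap uniform_baseline
#      14   0.641           0.1165
#      12   0.638           0.1022
#      10   0.584           0.0853
#       8   0.620           0.0669
#       6   0.599           0.0512
```

At every insertion count, well over half of the saliency mass falls on the
inserted lesions, versus the 5–12 % a uniform map would score.

Batch evaluation over a manifest of images, and the per-grade report tables
(per-model means of Entropy, Recall, Dice, AOPC over the quality methods),
come from `run_pipeline()`; a thin command-line wrapper with verbs
`synth-fundus`, `evaluate`, `trend` and `summarize` is installed at
`inst/cli/fundus_xai.R`.

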