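---
title: "Probing content and style in non-figurative drawings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing content and style in non-figurative drawings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What this package does

Non-figurative drawings -- scribbles produced by non-human primates or very
young children -- carry structured variation that hand-crafted features
(loop counts, fan patterns) capture poorly and with an anthropocentric bias.
`scribbleprobe` implements a deep-feature alternative: every drawing is
pushed through a frozen VGG19-style convolutional network and three
complementary questions are asked of the representation.

1. **Can a small trained head classify the drawings?** A transfer-learning
   head (global average pooling, batch normalization, one hidden FC layer,
   softmax) is trained on the frozen features (`train_head()`).
2. **Where in the network does the class signal live?** Each layer's
   activations are flattened, reduced by PCA to 80% explained variance and
   fed to a linear SVM scored by stratified 10-fold cross-validation
   (`probe_layers()`), for both RGB and NTSC-grayscale inputs; a regression
   of accuracy on depth summarizes the trend (`slope_test()`).
3. **Is it the content or the rendering style?** The same probe is run on
   Gram matrices `G = t(F) %*% F` of each conv layer's feature maps
   (`gram_probe_layers()`), the classic texture/style summary that discards
   spatial layout.

Every comparison against chance uses the 5x2cv paired t-test
(`paired_5x2cv_ttest()`) with the most-frequent-class dummy as the
reference.

The corpus the methodology targets (1299 orangutan drawings labeled by
season: 374 autumn, 269 spring, 284 summer, 372 winter; 907/392
train/validation split) is not publicly deposited, so the package ships a
synthetic scribble generator that emulates its statistical skeleton and
makes every stage testable end to end.

## The synthetic scribble generator

`render_scribble()` draws each stroke as a constant-speed random walk: the
heading angle receives i.i.d. Gaussian increments with standard deviation
`curvature_scale` (radians per step), the walk reflects at the canvas
border, and a hard-edged disc of the stroke width is stamped at every step
-- no anti-aliasing, so coverage is an exact pixel count. One palette color
is drawn per stroke (crayon-like behaviour; the corpus analyses speak of a
drawing's *main* color). The background is near-white (245,245,245) rather
than pure white so that ink/background thresholding has no ties.

Per-image seeds are derived from the dataset seed and the image index by a
fixed integer hash, so a dataset is bit-exactly reproducible from one
integer, in any rendering order.

The presets isolate which statistic separates the four season classes:

| preset       | palette                  | stroke shape            | coverage |
|--------------|--------------------------|-------------------------|----------|
| `paperlike`  | green-dominant in summer/winter, pink-dominant in spring/autumn | counts, widths and curvature all differ | free |
| `null`       | identical                | identical               | free     |
| `color-only` | one distinct hue/season  | identical               | free     |
| `shape-only` | identical                | counts/widths/curvature differ | free |
| `style-only` | identical                | only curvature differs  | matched target 0.25 |

Two constructions deserve emphasis. The `color-only` hues were found by
integer search so that all four have NTSC luminance *exactly* 110.000;
their grayscale renderings are therefore statistically identical and any
grayscale probe accuracy above chance would indicate a bug, not a class
signal. The `style-only` preset holds palette, stroke width and total ink
coverage fixed and varies only the walk curvature (0.04, 0.18, 0.5, 1.2
rad/step across seasons), so classes differ in large-scale stroke layout --
long straight sweeps versus tight squiggles -- while local ink statistics
match.

The corpus gives no quantitative stroke statistics per season, so all
stroke-model magnitudes (counts 8-32, widths 2-10 px, step length 2 px,
40-110 steps per stroke) are free parameters chosen once to produce
plausibly scribble-like images at moderate coverage; they are part of the
package's study definition, not estimates of the original drawings.

What the generator does *not* emulate: crayon texture and pressure, paper
grain, keeper identity or zoo events (documented confounders of the real
corpus), or any drift over years. Passing recovery tests therefore shows
the *pipeline* extracts the signal each preset plants; it does not certify
accuracies on real drawings.

## Standardization and splits

`standardize()` reshapes any 3-channel raster to 224 x 224 x 3. Non-square
boards are stretched (both axes resampled independently, bilinear) by
default; `mode = "crop"` center-crops first. Stretching was chosen as the
simplest deterministic reading of "reshaped to squares"; both modes are
exposed because the original preprocessing is not fully specified.

`to_grayscale_ntsc()` computes `Y = 0.299 R + 0.587 G + 0.114 B`, rounds
half away from zero, clamps to [0, 255] and replicates the channel three
times to preserve the network's input shape. The rounding rule makes the
conversion a bit-exact contract (and idempotent up to one gray level).

`split_train_val()` performs a stratified split with largest-remainder
allocation: each class's share of either subset matches its corpus share
within one image. With the corpus counts this reproduces the 907/392 split
with autumn at 28.8% of both subsets.

## The backbone

`build_backbone()` builds the canonical 16-conv-layer geometry (widths
64,64,128,128,256x4,512x4,512x4; all kernels 3x3 with padding 1; 2x2 max
pooling after each of the 5 blocks) plus the two hidden FC stages of width
4096. Probed activations are taken **post-ReLU** (the conventional choice;
the protocol being mirrored does not state it). Feature maps are flattened
row-major and concatenated in channel order; the conv1 activation vector of
a 224 x 224 image has length 64 x 224^2 = 3,211,264 and the length
decreases monotonically to 100,352 at conv16.

`weights_source = "seeded_random"` draws He-scaled Gaussian kernels
(`sd = sqrt(2 / fan_in)`) with zero biases, fully reproducible from one
seed -- the mode all tests run in, since ImageNet weights cannot be bundled.
`"pretrained"` accepts a user-supplied weight file in the package's layout.
The 25088 x 4096 FC1 weight matrix is generated chunk-wise from the seed at
extraction time so it never has to be stored.

Because conv1/conv2 activation matrices are too wide for PCA at full size,
`subsample_activations()` keeps a random 50% of activations -- one shared
index set across images, preserving feature correspondence -- and validates
the reduction: the 50 pooled means of repeatedly subsampled vectors are
compared to the original pooled mean by a one-sample t-test, which must be
non-significant. The per-repeat means are computed from accumulated column
sums, which is algebraically identical to gathering the full vectors and
keeps conv1 memory at `n x 1.6M`.

## The transfer head

The head is: global average pooling of the final 7 x 7 x 512 block (512
features; read as *global* pooling since a local pool would leave the FC
size unspecified) -> batch normalization -> FC(2048) with L2 penalty 0.1
and ReLU -> dropout 0.2 -> softmax. Training uses SGD (learning rate 0.1,
batch size 16), categorical cross-entropy, and early stopping after 3
epochs without validation-accuracy improvement (epoch cap 50); the weights
of the best validation epoch are returned. Because the backbone is frozen,
pooled features are computed once and cached, and flip augmentation is
implemented by enumerating the flip group (identity/h/v/hv) over the
training features -- the deterministic fixed point of per-epoch random
flipping. Augmentation never touches validation images. Batch-norm
statistics move only in training mode.

## Probing methodology and its conventions

* **PCA**: fitted on all images before cross-validation, exactly as in the
  protocol this package mirrors; this leaks unlabeled feature structure
  across folds, so `leakage_free = TRUE` refits PCA inside each training
  fold for users who want the conservative variant. For p >> n matrices the
  decomposition uses the n x n inner-product form. Component signs are
  fixed (largest-magnitude score positive) for run-to-run stability.
* **SVM**: linear kernel, cost 1, on PCA scores standardized to unit
  variance (margins are scale-sensitive). Multiclass handling is libsvm's
  pairwise one-vs-one. Kernel and cost are exposed.
* **Folds**: stratified, seeded; per-fold class proportions within one
  sample of the dataset's. `n_folds` equal to the sample count gives
  leave-one-out.
* **Depth regression**: layer indices conv1..conv16 -> 1..16, FC1 -> 17,
  FC2 -> 18; OLS of mean accuracy on index with a two-sided t-test on the
  slope. Slope tests are reported for conv-only and conv+FC subsets, since
  the source protocol does not state which entered its regression. A
  zero-residual zero-slope profile returns p = 1 by convention; an exact
  nonzero-slope line returns p = 0.
* **5x2cv paired t-test**: five seeded stratified 50/50 splits, both
  procedures trained and evaluated on identical splits with the roles of
  the halves reversed; `t = d11 / sqrt(mean(s_i^2))` on 5 df. The numerator
  is the first fold difference of the first replication, so the statistic
  depends on the seeded replication order; the seed is stored in the result.
  The sign convention is "procedure A minus procedure B"; swapping the
  procedures negates t and preserves p. Degenerate zero-variance cases are
  flagged (p = 0 if the numerator is nonzero, t = 0, p = 1 otherwise).
* **Multiple testing**: per-layer dummy comparisons are reported
  uncorrected, matching the mirrored protocol; `add_holm_column()` appends
  a Holm-adjusted column for transparency.
* **Gram orientation**: F is N x C with flattened maps as columns, so
  `t(F) %*% F` is C x C and each entry is the inner product of two feature
  maps -- the only reading consistent with interpreting entries as map
  correlations. No normalization by N or C is applied by default (exposed
  as an option); the full C^2 matrix is flattened without deduplicating the
  symmetric half.

## Problem sizes used by the tests and the acceptance script

The test suite and `scripts/acceptance.R` run everything with the seeded
random backbone at desk scale, a deliberate package choice: conv1 probes
use 10-12 images per class and 3 dataset seeds; Gram depth profiles use 12
per class over layers conv{1,3,5,7,9,11,13,16}; the end-to-end pipeline
smoke corpus is 4 per class with 4-fold cross-validation. These sizes give
Monte-Carlo error around +/-0.05-0.1 on probe accuracies, which the
recovery margins (dummy + 0.05, chance +/- 0.10) are set against.

## Known limitations

* **Random versus pretrained deep features.** With seeded random weights,
  probe accuracy on style-varied corpora rises steeply from conv1 (at
  chance, by construction) to the mid-stack (~conv5-7) and then *declines*
  toward conv16: random deep features are noisy projections that lose
  spatial resolution (14 x 14 at conv16) without gaining the semantic
  abstraction trained filters provide. A monotone accuracy increase into
  the deepest layers -- the signature reported for ImageNet-trained
  backbones -- should therefore not be expected from the random-weights
  configuration; the accuracy-versus-depth slope over the full stack is
  positive but typically non-significant at these sample sizes. The
  mid-stack rise (chance to ~0.6) is the robust random-weights analogue.
* The original drawings are not deposited; headline accuracies on that
  corpus (41.6% season, 66% binary subgroup, 94.8% coverage) are not
  reproducible here and are not targets of the test suite.
* The "test set" of the mirrored protocol is taken to be its 392-image
  validation split; the two are assumed identical.
* The generator plants independent images; real corpora have temporal
  autocorrelation (sessions, years) that stratified splitting ignores.
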