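---
title: "Methods: an attention-enhanced encoder–decoder for lung field segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an attention-enhanced encoder-decoder for lung field segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Automated delineation of the lung fields in a chest radiograph (CXR) is the
first step of most computer-aided thoracic analyses. The task is binary
semantic segmentation: every pixel of an `H × W` radiograph is classified as
lung field (foreground) or not. The difficulties are well known — lung shape
and size vary between patients, severe disease produces bright opacities
inside what is anatomically still lung, and foreign objects occlude the
field.

`cxrseg` implements an encoder–decoder convolutional network with three
additions over a plain U-Net-style baseline:

* **Encoder.** Three backbone stages produce feature maps `s1, s2, s3` at
  strides 2, 4 and 8 with channel widths `C, 2C, 4C`; 1×1
  channel-harmonizing convolutions join consecutive stages. A registry
  offers miniature offline versions of several backbone families
  (`efficientnet`, `resnet`, `densenet`, `mobilenet`) plus a plain
  `simple-conv` stack; all are trained from scratch — no weights are
  downloaded, and requesting pretrained weights is a configuration error.
* **Transformer attention module (TAM)** at the bottleneck. The deepest
  feature map (stride 8, `4C` channels) is flattened to `T = (H/8)(W/8)`
  tokens, a learned additive positional encoding is applied, and tokens are
  linearly projected to queries, keys and values. The attention map is the
  row-softmax of `Q Kᵀ / √d_k` with `d_k` the per-head channel count; values
  aggregated under this map are reshaped back to the input shape and added
  to the input (residual). Every attention row is a probability
  distribution; with the positional encoding disabled the block is exactly
  permutation-equivariant in the tokens.
* **Spatial enhancement module (SEM)** on each skip connection. A 3×3
  conv–BN–ReLU stem, parallel 3×3 average and max pooling (stride 1, same
  padding) concatenated and fused by a second conv–BN–ReLU, multiplied by a
  sigmoid channel gate computed from a global average pool of the input, and
  added back onto the input. Shape is preserved by construction.
* **Multi-scale feature fusion block (MS-FFB)** in the decoder. Three
  parallel branches with kernel sizes `k = 2i − 1 ∈ {1, 3, 5}`; each branch
  is a standard `k×k` convolution and a depthwise-separable `k×k`
  convolution, each followed by activation and batch normalization, and the
  branch outputs are summed. The decoder concatenates the (optionally
  SEM-enhanced) skip with the MS-FFB output of the upsampled deeper stream
  at each of the three levels, and a 1×1 sigmoid head after a final ×2
  upsampling produces the probability grid.

The ablation ladder of variants — `BL` (single-scale decoder, plain skips,
no attention), `MBL` (+ MS-FFB), `MBL+TAM`, `MBL+SEM`, `full` — is a
first-class configuration axis, and parameter counts increase strictly along
it.

## Evaluation

Five scores are computed from pixel confusion counts: Jaccard
`J = TP/(TP+FP+FN)`, Dice `D = 2TP/(2TP+FP+FN)`, accuracy, sensitivity and
specificity. Per image, `D = 2J/(1+J)` holds exactly. Two aggregations are
always reported side by side — the per-image mean and the pooled variant
(counts summed first) — because published tables rarely say which they use.
When truth and prediction are both empty, `J = D = Sn = 1` (vacuous
agreement) so blank images do not produce undefined ratios. Overlays colour
TP green, FP red, FN blue and TN black.

## Training regimen

Adam with initial learning rate 0.001, up to 60 epochs by default. If the
monitored validation quantity (validation Jaccard by default) fails to
improve for 5 consecutive epochs the learning rate is multiplied by 0.25;
training stops early after 12 stagnant epochs, and the best-monitor weights
are checkpointed and restored. The loss is binary cross-entropy, optionally
plus one minus the soft Dice score (`bce+dice`, equal weights, smoothing
constant 1) — the loss is a free choice here, and `bce+dice` is the standard
recommendation for binary segmentation with a sigmoid head when foreground
is a minority class. The training set is expanded five-fold before
training: contrast ×0.9, contrast ×1.1, horizontal flip and vertical flip,
with masks transformed in lockstep (contrast never touches a mask).
Augmentation happens strictly within partitions, after the split, so no
augmented copy of a training image can leak into validation or test.

The split rule is `n_val = n_test = round(n/10)`, training the remainder,
with a seeded shuffle. This reproduces the published partition sizes of all
four reference datasets (138 → 110/14/14, 6500 → 5200/650/650,
662 → 530/66/66, 1084 → 868/108/108); the often-quoted 80/10/20 header
cannot be taken literally since it sums to 110%.

## Numerical design choices

* **Automatic differentiation.** No deep-learning framework is used: the
  package carries a small reverse-mode autodiff engine over dense
  `(batch, height, width, channel)` arrays. Convolutions are im2col patch
  matrices multiplied through BLAS; every operation's gradient is verified
  against central finite differences in the test suite, end to end through
  the full network.
* **Stage geometry.** The three stages sit at strides 2/4/8 and the
  bottleneck at stride 8 — the only assignment under which three decoder
  fusions plus one final ×2 upsampling return exactly to full resolution.
* **Upsampling.** The decoder's "un-pooling" is implemented as ×2
  upsampling, nearest-neighbour by default with bilinear as an option
  (no pooling indices exist that could be un-pooled). Note a consequence
  for small images: with nearest-neighbour upsampling the prediction head
  (1×1 convolution after the last ×2 upsampling) emits probabilities that
  are constant over 2×2 blocks, so predicted boundaries are quantized to
  2-pixel resolution. At 256×256 this is negligible; at the miniature sizes
  used for fast self-tests it caps the achievable overlap, which is why the
  scaled-down convergence study below uses the bilinear option.
* **Attention orientation.** The attention map is token-by-token
  (`T × T`), softmax over the last axis; `d_k` is the per-head channel
  count; a residual connection and a learned positional encoding are on by
  default and configurable. Multi-head attention splits channels evenly.
* **Normalization order.** In the MS-FFB the activation is applied before
  batch normalization (matching the block's published formulation);
  `bn_after_relu = FALSE` restores the conventional conv–BN–ReLU order.
  SEM and the encoder stages use the conventional order.
* **SEM gate.** The gate convolution acts on the 1×1×`C` global-pool
  vector as a 1×1 convolution and is broadcast over space (a spatial kernel
  on a 1×1 input would be degenerate).
* **Thresholding.** A probability exactly equal to the binarization
  threshold is foreground.
* **Channel widths.** The published description never fixes `C`; the
  default is `C = 32` with per-stage doubling, fully configurable. Printed
  parameter totals of the original work therefore cannot be matched
  exactly; the package asserts the ladder's *ordering* instead, which is
  width-independent over a wide range.
* **"Reduce by a quarter".** Read as multiply-by-0.25; the ×0.75 reading is
  available by setting `lr_factor = 0.75`. "60 iterations" is read as 60
  epochs.

## The phantom generator

Real CXR datasets cannot ship with a package, so the generator produces
radiograph-like phantoms with exact ground truth: two rotated-ellipse lung
lobes (dark, as lung fields appear on a radiograph) over a textured thorax
background with faint rib stripes, per-image contrast jitter, and — with
configurable probability — a bright Gaussian opacity placed strictly inside
the lung field whose mask is deliberately *not* altered (diseased tissue is
still lung field). A lesion mode produces a single irregular bright blob as
a stand-in for tumour-segmentation data. Generation is fully determined by
`(spec, seed, index)` and files are byte-identical across runs.

What the phantoms emulate: two disjoint foreground components with 10–45%
coverage, variable lobe size and rotation, contrast variation, high-intensity
pathology inside the foreground. What they do not emulate: real anatomy
(mediastinum, diaphragm curvature, clavicles), acquisition physics, foreign
bodies. Tests passing on phantoms therefore verify the pipeline and the
optimization machinery, not clinical performance.

## Scaled-down study sizes

All self-contained studies run on one CPU, so sizes are chosen small: module
tests use feature maps from 1×1 up to 32×32; the end-to-end forward contract
is exercised at the full 256×256×3 input with `C = 16`; the convergence
study trains the `full` variant with the `simple-conv` backbone on 8 lung
phantoms at 32×32, `C = 8`, `bce+dice` loss, Adam at 0.001, full-batch, at
most 300 steps, with the bilinear decoder option for the boundary-resolution
reason above. The overfitting target (training Dice ≥ 0.95) checks that the
assembled network, gradients and optimizer can drive the loss to a near
interpolating solution; it says nothing about generalization. The plateau
schedule and early stopping are disabled for this study (constant learning
rate), since an overfitting-capacity check is not a model-selection run.

## Known limitations

* CPU-only and modest speed: the engine is meant for correctness,
  experimentation and teaching-scale problems, not for training at
  256×256 over thousands of images.
* Batch normalization uses per-batch statistics with running averages for
  inference; very small batches give noisy statistics.
* The miniature backbones share only the characteristic block structure of
  the families they are named after; they are not the published networks.
* Published benchmark scores on the external CXR datasets require those
  datasets and long training runs, and are out of scope for the package's
  self-tests.
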