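# cxrseg

Semantic segmentation of lung fields in chest radiographs with an
attention-enhanced encoder–decoder network, implemented natively in R.

## The problem

Delineating the lung fields in a chest X-ray (CXR) is the entry point of
most automated thoracic analyses (tuberculosis screening, COVID-19
assessment, cardiomegaly measurement). The task is binary semantic
segmentation under awkward conditions: lung shape and size vary across
patients, severe disease paints bright opacities inside what is still lung,
and hardware occludes the field. `cxrseg` is for researchers who want a
fully inspectable, dependency-light implementation of a modern segmentation
architecture — every forward and backward pass is plain R over dense arrays,
verified against finite differences — together with the full experimental
scaffolding: metrics, data pipeline, training regimen, synthetic phantoms
and an ablation harness.

## The model

An encoder–decoder with three additions over a U-Net-style baseline:

* **Encoder** — three backbone stages (miniature offline versions of
  EfficientNet/ResNet/DenseNet/MobileNet blocks, or a plain conv stack)
  produce feature maps *s1, s2, s3* at strides 2/4/8 with channel widths
  *C, 2C, 4C*, joined by 1×1 channel-harmonizing convolutions.
* **TAM** (transformer attention module) at the bottleneck — tokens =
  flattened stride-8 feature map plus a learned positional encoding;
  scaled dot-product self-attention `softmax(QKᵀ/√d_k)V` with residual;
  every attention row sums to 1.
* **SEM** (spatial enhancement module) on each skip — parallel 3×3
  max/average pooling fused by conv–BN–ReLU, weighted by a sigmoid channel
  gate from a global average pool, added residually to the input.
* **MS-FFB** (multi-scale feature fusion block) in the decoder — three
  branches with kernels k = 2i−1 ∈ {1, 3, 5}, each a standard plus a
  depthwise-separable convolution, summed; the decoder concatenates each
  SEM-enhanced skip with the fused upsampled stream, and a 1×1 sigmoid head
  returns an H×W probability grid.

Evaluation uses the five standard scores from pixel confusion counts —
Jaccard J = TP/(TP+FP+FN), Dice D = 2TP/(2TP+FP+FN) (= 2J/(1+J) per image),
accuracy, sensitivity, specificity — with per-image-mean and pooled
aggregation both reported. Training follows Adam (initial lr 0.001, up to
60 epochs), learning rate ×0.25 after 5 stagnant validation epochs, early
stopping, best-weights checkpointing, and a five-fold augmentation policy
(contrast ×0.9/×1.1, horizontal/vertical flips).

## Worked example

Generate a tiny phantom dataset, train the full variant on it, and evaluate:

```r
library(cxrseg)

root <- file.path(tempdir(), "phantoms")
generate_phantoms(phantom_spec(size = 32, seed = 1), n = 10, out_dir = root)
manifest <- build_manifest(root, seed = 1)            # 8 train / 1 val / 1 test
                                                      # (training rows x5 tags)
mc <- model_config(input_size = 32, base_channels = 8,
                   backbone_name = "simple-conv", variant = "full",
                   upsample = "bilinear")
tc <- train_config(max_epochs = 40, batch_size = 8,
                   loss_name = "bce+dice", seed = 1)
fit <- cxrseg_fit(manifest, model = mc, config = tc, target_size = 32)
print(fit)
#> Fitted segmentation network (full variant): 24 epoch(s), stopped by early_stop
#>   best monitor (val_jaccard): 0.9304   final lr: 6.25e-05
```

Training ran 24 epochs, stopped early, and the plateau schedule had cut the
learning rate from 1e-3 to 6.25e-5 (two ×0.25 reductions). Evaluating the
held-out phantom:

```r
pm <- predict(fit, test_image)              # probabilities + binary mask
report <- evaluate_masks(list(pm$binary), list(test_mask))
print(report)
#> Segmentation report over 1 image(s)
#>   mean J=90.14% D=94.81% Acc=97.17% Sn=97.79% Sp=96.95%
render_overlay(pm$binary, test_mask, "overlay.png")   # TP green, FP red,
                                                      # FN blue, TN black
count_parameters(mc)
#> [1] 104625
```

A Jaccard index of 90% on an unseen phantom after 24 epochs on eight
training images is what this miniature configuration is expected to reach;
the scores mean 90% overlap-over-union (J), 95% of the harmonic overlap (D),
and near-balanced sensitivity/specificity.

There is also a command-line interface (`exec/cxrseg`) with sub-commands
`train`, `eval`, `predict`, `overlay`, `phantom`, `split` and `ablate` (the
Table-style five-variant ablation ladder), driven by a single YAML config.

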