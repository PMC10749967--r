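# cocoseg

Semantic segmentation of coconut CT slices into their internal organs, with
morphometric quantification of the segmented embryo.

Coconut breeding programs need to follow the development of the fruit's
internal organs — solid endosperm (meat), liquid endosperm (water), the
haustorium (the spongy absorber a germinating seed grows into the cavity),
and the embryo — without cutting the fruit open. X-ray computed tomography
makes the interior visible; turning CT slices into per-organ measurements
then requires pixel-accurate semantic segmentation. `cocoseg` implements an
improved DeepLab V3+ encoder–decoder for this task, the compound loss it is
trained with, the full confusion-matrix evaluation suite, and the scan-line
morphometry applied to the segmented images. Because no public coconut CT
dataset exists, the package also ships a parametric **phantom generator**
that renders synthetic coconut slices with exact ground truth, so every
stage of the pipeline is testable end to end.

The network and its training loop are implemented natively in R on top of
BLAS matrix products (im2col convolutions with reverse-mode automatic
differentiation); no external deep-learning runtime is required.

## The model

Relative to plain DeepLab V3+, three modules are changed or added:

* **DASPP** — a densely connected atrous spatial pyramid replaces ASPP.
  Layer *k* (3×3 convolution at dilation *d_k*, with *d*₁ < … < *d_L* =
  3, 6, 12, 18, 24) consumes the concatenation of the module input with the
  outputs of all previous layers, so its input width is C₀ + (k−1)·g for
  growth g; a 1×1 convolution fuses the input plus all layer outputs.
* **CBAM** — convolutional block attention: channel gates
  σ(MLP(avgpool F) + MLP(maxpool F)) followed by spatial gates
  σ(conv₇ₓ₇[mean_c F ; max_c F]), applied to the high-level features before
  the pyramid and to the low-level features before decoder fusion.
* **RRM** — a residual refinement module after the decoder output: a
  4-stage encoder (non-overlapping 2×2 max pooling) and 4-stage decoder
  (bilinear upsampling), each stage one 3×3 convolution of 64 filters with
  batch norm and ReLU, producing a residual added to the coarse class
  scores to sharpen organ boundaries.

Training minimises `w · Dice + (1 − w) · focal` with w = 0.7, using Adam
(learning rate 1e-4, β₁ = 0.9, batch 4, 150 epochs at 256×256 in the
reference profile). Evaluation reports per-class IoU and pixel accuracy
plus mIoU, mPA and support-weighted F1, all derived from one accumulated
confusion matrix `p_ij` (pixels of true class *i* predicted as class *j*).

Masks are color-coded: background black, solid endosperm red, liquid
endosperm blue, haustorium yellow, embryo green `(0, 255, 0)`. Embryo
height is measured by scanning rows top-down and bottom-up for the first
and last green pixel (points A and B; inclusive row count), after an
optional principal-axis rotation for tilted embryos, and is converted to
millimetres by the scanner's in-plane scale.

## Worked example

A miniature run (60 phantom slices at 32×32, 5 epochs, ~2 minutes on one
CPU):

```r
library(cocoseg)
manifest <- generate_dataset(60, "phantoms", seed = 7, image_size = 32)
split <- split_dataset(manifest, ratio = 0.8, seed = 7)

model <- build_model(desk_net_config(input_size = 32), seed = 7)
fit <- train_model(model, split$train, split$test,
                   train_config(desk_profile = TRUE, epochs = 5, seed = 7),
                   root = "phantoms")
report <- evaluate(fit$model, split$test, root = "phantoms")
print(report)
```

```
<coco_metrics> (12 images)
  background         IoU 95.00  PA 95.37
  solid_endosperm    IoU 78.22  PA 95.62
  liquid_endosperm   IoU 82.56  PA 90.89
  haustorium         IoU  0.00  PA  0.00
  embryo             IoU 32.52  PA 33.50
  mIoU 57.66 | mPA 63.08 | F1 92.97  (percent)
```

Each organ row is its intersection-over-union and pixel accuracy (recall)
in percent; the aggregates average over the five classes, background
included. At this miniature scale the large ring-shaped organs are already
segmented well while the rare small organs (haustorium appears only in
late-month slices, and the embryo spans a handful of pixels at 32×32) are
not — which is exactly the class-imbalance behaviour the Dice-weighted loss
and the attention/refinement modules are there to address at realistic
resolution. The desk profile proper (200 training slices at 64×64, 10
epochs, ~15 minutes) reaches a test mIoU of about 0.87 against a
majority-class baseline of 0.11.

Morphometry on a segmented (or ground-truth) semantic image:

```r
sem <- mask_to_color(load_manifest_slices(split$test[1, ], 32,
                                          root = "phantoms")[[1]]$mask)
measure_embryo(sem, mm_per_pixel = 0.4)
#> # A tibble: 1 × 8
#>   organ  pixel_count height_px height_mm a_row b_row rotation_applied_deg
#> 1 embryo          23         6       2.4    14    19                    0
```

`tidy()`, `glance()` and `autoplot()` methods are available for metric
reports and training logs; `run_ablation()` trains the four module
combinations (DASPP+CBAM, RRM+CBAM, DASPP+RRM, all three) under one seed
and returns the ablation table. A command-line interface with `generate`,
`split`, `train`, `evaluate`, `ablation`, `segment` and `extract` commands
is installed at `system.file("cli", "cocoseg.R", package = "cocoseg")`.

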