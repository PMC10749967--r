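---
title: "Methods: coconut CT organ segmentation with an attention-augmented DeepLab V3+"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coconut CT organ segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cocoseg` segments axial CT slices of coconuts into five classes —
background, solid endosperm, liquid endosperm, haustorium (absorber), and
embryo — and quantifies the segmented organs. This vignette is the
package's own account of the method: the model, the synthetic data it is
validated on, the conventions behind every metric, and the design decisions
taken where the problem left the design open.

## The segmentation model

The network is a DeepLab V3+ encoder–decoder with three modifications.

**Backbone.** A residual convolutional encoder produces low-level features
at stride 4 and high-level features at stride 16. The backbone family is
deliberately configurable (`backbone_depth`): `"small"` (stem channels
16/32/64/96, one residual block per stage, ~1.5 M parameters in the full
model) runs usefully on a single CPU; `"standard"` (32/64/128/256, two
blocks per stage) is the realistic setting. CT slices are grayscale, so
the stem takes one input channel; `in_channels = 3` replicates the
grayscale image for workflows that expect RGB-shaped stems.

**Dense atrous pyramid (DASPP).** The high-level features pass through a
cascade of 3×3 atrous convolutions whose dilation rate increases layer by
layer (default 3, 6, 12, 18, 24 — rates adopted from the dense-ASPP
literature, since the cascade only fixes that rates increase). Layer $k$
receives the concatenation of the module input with the outputs of all
previous layers, so its input width is $C_0 + (k-1)\,g$ with growth $g$
(`daspp_growth_channels`, default 64); a 1×1 convolution fuses the input
together with every layer output. Dense connectivity keeps small effective
receptive fields in the mix even at large nominal dilation, countering the
sampling sparsity of high-rate atrous kernels. With `use_daspp = FALSE`
the module degrades to a plain parallel ASPP (1×1 branch plus dilations
6, 12, 18) for ablation.

**CBAM.** Convolutional block attention recalibrates a feature map $F$
sequentially: channel gates
$M_c = \sigma(\mathrm{MLP}(\mathrm{avgpool}\,F) + \mathrm{MLP}(\mathrm{maxpool}\,F))$
with a shared two-layer perceptron (bottleneck ratio `cbam_reduction`,
default 16), then spatial gates
$M_s = \sigma(\mathrm{conv}_{7\times7}[\mathrm{mean}_c F'; \mathrm{max}_c F'])$,
giving $F'' = M_s \odot (M_c \odot F)$. Where CBAM sits is a genuinely
open point, so the package applies it at the two places where features
cross module boundaries — the high-level features before the pyramid and
the low-level features before decoder fusion — and exposes each insertion
point as its own switch (`cbam_on_high`, `cbam_on_low`). All gates are
strict sigmoids, so attention can only attenuate, never amplify.

**Decoder.** The pyramid output is upsampled 4× bilinearly, concatenated
with a 1×1-projected copy of the low-level features, refined by two 3×3
convolutions, projected to class scores, and upsampled 4× again. The two
4× steps are the DeepLab V3+ convention; large upsampling factors blur
boundaries, which is precisely the weakness the refinement stage targets,
so the factors are kept and the repair is delegated to the RRM.

**Residual refinement module (RRM).** The full-resolution class-score map
enters a small symmetric encoder–decoder: four encoder stages
(non-overlapping 2×2 max pooling) down, a bridge, and four decoder stages
(bilinear 2× upsampling) back up, each stage exactly one 3×3 convolution
with 64 filters, batch normalisation and ReLU. A final 3×3 convolution
maps back to class scores and is **added** to the input (residual design),
so the module learns a boundary correction rather than a new segmentation.
Feeding the RRM the class scores (rather than decoder features) follows
from its placement after the decoder output; the final convolution is
initialised near zero so refinement starts close to the identity. The
test suite pins the identity property exactly at zero initialisation.

All feature maps are stored channels-last, `(H, W, N, C)`; convolutions are
im2col + BLAS gemm with analytic backward passes, and every operator's
gradient is verified against central finite differences in the tests.

## Training objective and optimisation

The loss is $w\,L_{\mathrm{Dice}} + (1-w)\,L_{\mathrm{focal}}$ with

$$L_{\mathrm{Dice}} = 1 - \frac{1}{K}\sum_k
  \frac{2\sum_i p_{ik} t_{ik} + \varepsilon}
       {\sum_i p_{ik} + \sum_i t_{ik} + \varepsilon}, \qquad
L_{\mathrm{focal}} = \frac{1}{M}\sum_i -(1 - p_{i,y_i})^{\gamma}
  \log p_{i,y_i},$$

where $p$ are softmax probabilities, $t$ the one-hot target, $\varepsilon
= 1$ the Dice smoothing constant and $\gamma = 2$ the focal exponent. The
published configuration states only that the combination carries "a
weight of 0.7"; the package assigns 0.7 to the **Dice term**, since Dice
is the term that counteracts the background/small-organ imbalance that
motivates the compound loss — and the weight is configurable for the
opposite reading. The focal parameters are unpublished; $\gamma = 2$ and
no per-class $\alpha$ weighting are the standard defaults and both are
exposed. The loss is zero exactly at the one-hot target, and the fused
softmax-plus-loss gradient is finite-difference checked.

Optimisation is Adam at learning rate 1e-4, batch 4, 150 epochs in the
reference profile. A stated momentum of "9" is not a valid momentum and is
read as the 0.9 first-moment coefficient ($\beta_1$) of the stated Adam
optimizer. No data augmentation is described, and none is applied.
Training selects the checkpoint with the best validation mIoU; whether the
original procedure did model selection is unstated, and best-validation is
the conservative default.

**Desk profile.** `train_config(desk_profile = TRUE)` with
`desk_net_config()` scales the experiment to one CPU: 64×64 inputs, the
small backbone, 10 epochs, batch 8 — and learning rate 1e-3, because a
250-step run from random initialisation is still in Adam's cold-start
regime at 1e-4; the tenfold rate is appropriate for this short schedule
and is part of the profile's definition, chosen with the profile itself.
The reference profile keeps the published 1e-4.

## The phantom generator

No public coconut CT dataset exists, so the package validates against a
parametric phantom (`phantom_spec()`, `generate_slice()`,
`generate_dataset()`) that emulates the geometry of an axial slice: a
bright shell/husk ring, a solid-endosperm ring lining it, a darker liquid
cavity, and optionally an embryo ellipse and a haustorium disc inside the
cavity. Labels follow the annotation scheme: the four organs plus
background; the shell is **rendered but labelled background**, since it is
not an annotation class. Images are per-organ mean intensities plus
additive Gaussian noise clipped to $[0,1]$ (the simplest controllable
corruption); the default means (background 0.05, liquid 0.25, haustorium
0.42, solid 0.55, embryo 0.70, shell 0.85, noise σ = 0.03) keep every pair
of classes separated by at least 2σ, and a validity check rejects specs
that violate this or the concentric nesting. Slice file names follow the
`color_month_id` convention, and the month drives geometry — older fruit
get a thicker solid-endosperm ring (less liquid), larger and more frequent
embryos, and a haustorium from month 8 — so some slices genuinely lack
organ classes, as in real developmental series. The exact month-to-geometry
mapping is the package's own.

Every slice carries exact ground truth: per-class pixel counts and the
embryo's inclusive row extent in pixels and millimetres. The default
`mm_per_pixel = 0.4` corresponds to a ~100 mm fruit spanning a 256-pixel
field of view; it is a dataset parameter, not a constant, because scanner
in-plane spacing is installation-specific.

What the phantom does **not** emulate: beam hardening, Hounsfield
calibration, texture inside organs, partial-volume effects at boundaries,
multiple fruits per slice, or 3-D coherence between slices. Passing tests
on phantoms therefore demonstrates that the pipeline's machinery is
correct and that the architecture can learn intensity-plus-shape classes;
it does not certify accuracy on scanner data.

## Evaluation conventions

All metrics derive from one confusion matrix $p_{ij}$ (pixels of true
class $i$ predicted as class $j$), accumulated entrywise over the test
set; per-image averaging is available as an option
(`evaluate(per_image = TRUE)`) since either reading of "test-set metrics"
is defensible. Per class: precision $= p_{ii}/\sum_j p_{ji}$ (column
sum), recall/PA $= p_{ii}/\sum_j p_{ij}$ (row sum), IoU $= p_{ii} /
(\text{row} + \text{col} - p_{ii})$ — the standard form; the printed IoU
equation in the source material is typographically garbled and the prose
definition ("ratio of intersection and union") is followed instead. mIoU
and mPA are unweighted means over all five classes **including
background** (consistent with published per-organ tables listing a
Background column). F1 is aggregated with support weights $r_i$ (class
$i$'s share of ground-truth pixels), the quantity the metric set defines;
unweighted macro-F1 is available. A $0/0$ ratio (class absent from both
truth and prediction) is undefined and **excluded** from means rather than
scored zero, so slices with missing organs do not penalise models. The
identity IoU ≤ PA holds per class by algebra and is asserted
property-style across random masks.

## Morphometry conventions

Embryo height scans rows top-down and bottom-up for the exact color
`(0, 255, 0)` (points A and B) and counts rows **inclusively**
($B - A + 1$): a one-pixel embryo has height 1, and a pixel-centered
vertical ellipse with semi-major $a$ spans $2a + 1$ rows. For tilted or
curved embryos, `align_embryo()` rotates the image so the embryo's
principal axis — the leading eigenvector of the second moments of its
pixel coordinates — is vertical, using nearest-neighbour resampling so
palette colors survive exactly; a manual angle override exists. When a
slice contains several disconnected embryo components (two fruits in one
image), the largest connected component is measured and the component
count reported. Conversion to millimetres is linear in `mm_per_pixel`.

## Numerical choices

* Convolutions use zero padding `dilation·(k−1)/2`, so spatial dims are
  preserved; spatial-attention maps are constant on constant inputs only
  beyond kernel reach of the border (zero padding breaks exact border
  constancy).
* Bilinear resizing uses the half-pixel-center convention with separable
  interpolation matrices; masks are always resized nearest-neighbour so
  no interpolated labels can appear.
* Batch norm: $\varepsilon = 10^{-5}$, running-statistics momentum 0.1;
  evaluation uses running statistics.
* Max-pool backward breaks ties toward the first window position;
  argmax class decisions break ties toward the lower class index.
* Softmax is computed with per-pixel max subtraction; focal
  probabilities are clamped at $10^{-8}$ before the logarithm.
* Weight init is He-scaled Gaussian, seeded; `build_model(seed = )` is
  bit-reproducible, and the training loop's only randomness is the
  seeded shuffle, so fixed-seed runs produce identical loss curves.

## Problem sizes used by the tests and the acceptance script

Unit tests exercise modules at 32×32 with small batches; gradient checks
run on toy tensors. The learning check and the acceptance script use the
desk profile: 250 phantoms at 64×64 split 8:2 (200 training slices), 10
epochs, batch 8 — sizes chosen so a complete from-scratch run finishes in
minutes on one CPU while still giving the small organs enough pixels to be
learnable. The ablation harness is exercised structurally (four variants,
bit-identical reruns) on a reduced 32×32 configuration; the full-size
ablation is available through `run_ablation()` and the CLI's `ablation`
command. The acceptance checks require the desk-profile model to reach
test mIoU ≥ 0.70 and to beat both the majority-class baseline and an
untrained network; this threshold is a property of the phantom task at
desk scale, not a published value.

## Known limitations

* The phantom's simplicity means desk-scale scores say nothing
  quantitative about scanner data; published full-scale results require
  the original dataset and GPU-scale training.
* The pure-R engine is single-threaded gemm-bound; the reference profile
  (256×256, 150 epochs) is functional but slow, and is not exercised by
  the tests.
* Strongly curved embryos are measured by their principal-axis extent;
  arc length along the curve is out of scope.
* One confusion matrix per run means very large and very small test
  images contribute proportionally to pixel counts, not equally per
  image, unless `per_image = TRUE`.
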