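---
title: "Fused two-branch segmentation of skin lesions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fused two-branch segmentation of skin lesions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionfuse)
```

## The problem

Dermoscopy images show a pigmented lesion against surrounding skin, and the
segmentation task is to recover a per-pixel binary mask of the lesion. Two
properties make this harder than generic blob detection: hair and other
dark curvilinear artifacts cross the lesion and the background, and the
intensity gap between lesioned and normal skin can be small. `lesionfuse`
implements a two-branch convolutional approach: two encoder–decoder
networks with different inductive biases are trained on the same data, and
their predictions are merged by an overlap-based post-processing step, the
idea being that the branches make partially independent mistakes.

## The two branches

Both branches are fully convolutional encoder–decoders over single-channel
(luma) inputs, with `depth` resolution levels, channel widths
`base_width * 2^(level-1)` capped at `max_width` (32 to 512 in the
reference configuration), 3×3 kernels, ReLU activations, skip
concatenation from each encoder level to its decoder mirror,
transposed-convolution upsampling, and a 1×1 convolution with a sigmoid
head, so outputs are per-pixel probabilities in (0, 1).

They differ deliberately:

* **V-Net2D** (`build_vnet2d()`): residual *stages* — one convolution at
  level 1, two at level 2, three at deeper levels — where the stage input
  is added to the stage output (a 1×1 projection aligns channel counts
  when they differ). Downsampling is a strided 2×2 convolution, the V-Net
  convention. Feature maps are normalized with **group normalization**
  (8 groups by default; the group count divides every width from 32 up,
  and is reduced automatically for narrower desk-scale models).
* **U-Net+ResNet2D** (`build_unet_resnet2d()`): the classic U-Net layout
  with every double convolution replaced by a two-convolution residual
  block, 2×2 **max-pooling** downsampling, and **batch normalization**
  with running statistics (momentum 0.1) used at evaluation time.

Weights are initialized with the Xavier/Glorot scheme,
N(0, 2/(fan_in+fan_out)) with zero biases, deterministically from the
spec seed. Inputs must be divisible by `2^(depth-1)`; the error message
suggests padding otherwise. The decoder convolution counts mirror the
encoder stage counts; this is a design choice where the topology was
genuinely open, made for symmetry and parameter economy.

The engine underneath (`src/ops.cpp`) is a compact CPU implementation:
im2col + GEMM convolutions, explicit reverse-mode backward passes for
every layer, verified against central finite differences (the test suite
checks full-network parameter gradients to ~1e-8 relative error at double
precision).

## Losses and metrics

Overlap quality is scored from pixel confusion counts: Dice
`2TP/(2TP+FP+FN)`, Jaccard `TP/(TP+FP+FN)` (related by `D = 2J/(1+J)`),
accuracy, sensitivity, specificity, and the challenge-style thresholded
Jaccard (scores below 0.65 count as 0 before averaging). When a class is
absent from both masks the corresponding score is defined as 1.

Training uses soft counts over sigmoid probabilities `p` and binary
targets `t`: `TP = Σpt`, `FP = Σp(1−t)`, `FN = Σ(1−p)t`. The Tversky
index `TP/(TP + αFN + βFP)` weights missed lesion pixels (α = 0.7)
against false alarms (β = 0.3); with α = β = 0.5 it reduces to soft
Dice. The fused training loss is

\[ L = w_{DL}\,(1 - \mathrm{softDice}) + w_{FTL}\,(1 - TI)^{\gamma}, \qquad
   w_{DL} = w_{FTL} = 1,\ \gamma = 0.75 . \]

Two numerical choices deserve a note. First, the focal exponent is
applied to the *complement* of the Tversky index, `(1−TI)^γ`, so γ = 1
recovers the plain Tversky loss exactly and γ < 1 amplifies the gradient
near good overlap; the alternative algebraic reading `1 − TI^γ` is
available via `form = "complement_power"` in `focal_tversky_loss()`.
Second, every soft ratio carries a smoothing constant ε = 1e-6 in
numerator and denominator, so empty-vs-empty comparisons are well defined
and gradients stay finite; analytic gradients of all three losses are
exported (`*_grad()`) and tested against finite differences at 1e-4
relative tolerance.

## Preprocessing and augmentation

The enhancement chain (`preprocess_pair()`) is: piecewise-linear contrast
stretch, unsharp-mask sharpening, resize, luma conversion — in that
order. The stretch maps the low percentile of intensities to 0 and the
high percentile to 255, linearly in between, monotonically; the default
band (2, 98) is the standard robust choice, and (0, 100) recovers a pure
min–max stretch. Breakpoints are per channel for colour inputs. Constant
images are returned unchanged with a warning, since the map is undefined.
Sharpening is unsharp masking, `out = clip(in + amount·(in − blur(in)))`
with a Gaussian blur of σ = 1 and amount 10 by default, addressing fuzzy
lesion edges; amount 0 is the identity. Images are resized bilinearly,
masks with nearest-neighbour so they stay strictly binary.

Training-set augmentation (`augment_dataset()`) composes five transforms,
each participating with probability 0.5, in a fixed order: horizontal and
vertical flips, rotation (uniform in ±30°), grid distortion (4×4 cells,
±8 px control points), elastic deformation (uniform fields smoothed with
σ = 4 and scaled by α = 30 px), and a lesion-boundary crop — the pair is
scaled by a factor in (0.8, 1.2), a window is centred on a uniformly
sampled lesion-edge pixel (a lesion pixel with a background 4-neighbour)
and resized back, guaranteeing both classes in every crop and sharpening
edge localization. All magnitudes are configuration, chosen as mild
standard values since no canonical settings exist. Every transform
applies one coordinate map to image (bilinear) and mask
(nearest-neighbour) through a single warping primitive with mirrored
borders, which is what makes the "identical geometry" invariant testable.
All randomness flows from one seed, so an augmented dataset is
bit-reproducible.

## Training

ADAM (β₁ = 0.9, β₂ = 0.999) at learning rate 1e-3 with batch size 4, the
reference configuration. The published full-scale run is quoted as
"100,000 epoch"; we read this as optimizer steps — at 72k augmented
images and batch 4, that is roughly five true epochs — and expose it as
`max_steps`. A `val_fraction` (default 0.2, matching the 80/20
train/validation protocol) is held out; the returned checkpoint is the
one with the best monitored dice, dice being the headline metric. An
optional dice target stops training early once reached. Non-finite losses
abort with the offending step number. Prediction thresholds sigmoid
probabilities at 0.5 by default (strictly greater, so threshold 0 yields
all-lesion and threshold 1 all-background).

## Prediction fusion

Each branch's thresholded mask is first cleaned of connected components
smaller than `min_component_size` (default 64 px at 512×512 — small
relative to any plausible lesion; scale it with the image area),
using an explicit BFS labeller with 8-connectivity by default. The final
mask is then assembled from the most-overlapping regions. Two concrete
rules are provided, since the qualitative description ("least related
points removed, most overlapping regions kept") admits both:

* `component_overlap` (default): a component `C` of either branch is
  retained iff `|C ∩ other|/|C| ≥ 0.5`; the fused mask is the union of
  retained components. This is region-level, matching the language of
  overlapping *regions*, and tolerant of small boundary disagreement.
* `pixel_and`: the pixel-wise intersection — the conservative fallback,
  with the provable guarantees that the fused mask is a subset of each
  branch and its specificity is at least the better branch's.

In both rules the fused mask never leaves the union of the inputs.
Filtering precedes overlap computation; the cleanup is shown on
single-branch outputs in the source procedure, and filtering first keeps
a small spurious blob from vetoing or inflating a region decision.

## Synthetic data

`generate_pair()` draws a skin-toned background, one star-convex lesion —
radius profile `r(θ) = r₀(1 + a·s(θ))` with `s` a low-order random
Fourier series normalized to unit amplitude — darker than the skin by a
`contrast` fraction, plus dark Bézier hair strokes (image only, never the
mask) and Gaussian sensor noise. Star-convexity guarantees a single
connected component and a known analytic area (`π r₀²` for a regular
disc, `E[π r²]` under the radius distribution), which the tests exploit.
Defaults: 128 px frames, radius 0.15–0.35 of the frame, border
irregularity 0.15, contrast 0.5, 3 hairs, noise σ = 8 — values chosen
once as a plausible mid-difficulty regime; `contrast` is the difficulty
dial (0.8 with low noise is separable by plain thresholding; 0.1 with
high noise is not).

What the generator does *not* emulate: colour texture inside the lesion,
vignetting, gel bubbles and rulers, multi-lesion scenes, and the
full-resolution statistics of real dermoscopy. Passing the desk-scale
pipeline tests therefore demonstrates that the machinery — losses,
gradients, training dynamics, fusion — is correct and that the method
behaves sensibly on controllable difficulty, not that the reported
full-scale ISIC accuracy is reproduced; that would require the external
dataset and GPU-scale training, which are out of scope here.

## Problem sizes used in the tests

The suite exercises desk-scale configurations chosen to keep the whole
battery in a few CPU-minutes while preserving every structural contract:
width-8, depth-3 branches; an overfit sanity run (8 pairs at 64×64,
200 ADAM steps, batch 4, three seeds per branch); and an end-to-end run
of 200 synthetic 96×96 pairs split 160/40 with early stopping at
validation dice 0.97. `scripts/acceptance.R` re-runs the end-to-end
computation from scratch under a caller-supplied seed.

## Known limitations

* The CPU engine is written for clarity and desk-scale sizes; full
  512×512, width-32 training is numerically identical but slow — the
  reference hardware for that regime is a GPU, and this package does not
  target it.
* Batch-norm evaluation uses running statistics accumulated during
  training; very short runs evaluate with few accumulated batches.
* No hair removal or colour-constancy preprocessing is provided; the
  networks are expected to learn around hair artifacts.
* Fusion is mask-level; probability-level ensembling (averaging the two
  sigmoid maps) is deliberately not implemented, to keep the
  post-processing faithful to the region-overlap formulation.
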