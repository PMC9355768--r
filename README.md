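# lesionfuse

Two-branch fused convolutional segmentation of skin lesions in dermoscopy
images, for researchers and engineers building or studying lesion
segmentation pipelines without committing to a deep-learning framework
stack: the package ships its own compact, fully tested CPU engine
(im2col/GEMM convolutions with exact reverse-mode gradients) in
R + Rcpp/Armadillo.

## What it implements

Automatic lesion segmentation is hard because hair artifacts cross both
lesion and skin, and the lesion-to-skin contrast can be low. `lesionfuse`
attacks this with a fusion design:

* **Two encoder–decoder branches** with different inductive biases —
  **V-Net2D** (residual stages with 1/2/3 convolutions per level, strided
  2×2 downsampling, group normalization) and **U-Net+ResNet2D** (U-Net
  topology with residual blocks, 2×2 max-pooling, batch normalization).
  Both: 3×3 kernels, ReLU, skip concatenation, transposed-convolution
  upsampling, sigmoid 1×1 head, Xavier initialization, channel widths
  doubling from 32 to a cap of 512 (configurable down to desk scale).
* **A fused training loss** combining Dice Loss and Focal Tversky Loss,

  `L = (1 − softDice) + (1 − TI)^γ`, `TI = TP/(TP + αFN + βFP)`

  with α = 0.7, β = 0.3, γ = 0.75, optimized with ADAM (lr 1e-3,
  batch 4).
* **The preparation recipe**: percentile contrast stretch → unsharp-mask
  sharpening (amount 10) → resize (512×512 reference) → luma; training
  augmentation by flips, rotation, grid distortion, elastic deformation,
  and lesion-boundary crops.
* **Overlap-based prediction fusion**: small connected components are
  removed from each branch's mask, then components are kept only where
  the branches agree (≥ 50 % component overlap, or a strict pixel-wise
  AND), yielding the final mask.
* **Evaluation** in the standard columns: Dice, Jaccard, thresholded
  Jaccard (0.65 rule), accuracy, sensitivity, specificity — per-image
  means and pooled counts.
* **A synthetic dermoscopy generator** (star-convex lesions with
  irregular borders, hair strokes, controllable contrast and noise) so
  the complete pipeline is testable at desk scale with no downloads.

## Worked example

Sixty synthetic 64×64 pairs, desk-scale branches (width 8, depth 3),
early-stopped fused-loss training, component-overlap fusion:

```r
library(lesionfuse)

pairs <- generate_dataset(60, synth_config(size = 64L, contrast = 0.8,
                                           noise_sigma = 6), seed = 7)
cfg <- pipeline_config(
  vnet_spec = model_spec("vnet2d", input_size = c(64L, 64L, 1L),
                         base_width = 8L, depth = 3L),
  unet_spec = model_spec("unet_resnet2d", input_size = c(64L, 64L, 1L),
                         base_width = 8L, depth = 3L),
  train = train_config(max_steps = 150L, eval_every = 25L,
                       early_stop_dice = 0.97),
  fusion = fusion_config(min_component_size = 16L),
  seed = 7L)
res <- run_pipeline(pairs, cfg)
round(do.call(rbind, res$report$mean), 3)
#>                dice jaccard t_jaccard accuracy sensitivity specificity
#> vnet2d        0.991   0.982     0.982    0.997       0.998       0.997
#> unet_resnet2d 0.988   0.977     0.977    0.996       1.000       0.994
#> fused         0.985   0.971     0.971    0.995       1.000       0.993
```

The rows are the two branches and the fused result on the held-out test
split (48 train / 12 test here); columns are per-image mean scores. On
this easy synthetic regime (contrast 0.8) all three segmenters are near
ceiling; the fusion step's value shows up in its guarantees — under the
pixel-AND strategy the fused specificity is provably at least the better
branch's, and small spurious blobs are removed before fusion.

Individual stages are exported too: `preprocess_pair()`,
`augment_dataset()`, `build_vnet2d()` / `build_unet_resnet2d()`,
`train()`, `predict_masks()`, `remove_small_components()`,
`fuse_predictions()`, `evaluate_predictions()`, plus the losses and their
analytic gradients (`fusion_loss()`, `fusion_loss_grad()`, ...). A thin
command-line wrapper lives at `inst/cli/lesionfuse.R`
(`synth`, `preprocess`, `augment`, `run`, `evaluate` subcommands). Real
data is read with `load_pairs()` from ISIC-style directories
(`<id>.jpg` + `<id>_segmentation.png`).

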