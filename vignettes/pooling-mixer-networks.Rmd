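---
title: "Pooling-mixer U-shaped networks: model, accounting, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooling-mixer U-shaped networks: model, accounting, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(poolunetr)
```

## The model

`poolunetr` implements a U-shaped 3D segmentation network of the
Swin-UNETR family in which the windowed self-attention token mixer can be
replaced by a parameter-free spatial average-pooling operator, following
the MetaFormer observation that the block template (norm, token mixer,
residual; norm, feed-forward, residual) carries most of the modeling power
regardless of the particular mixer.

The encoder embeds an `in_channels x D x H x W` volume with a strided
linear patch embedding (kernel 2, stride 2) into `C` channels at half
resolution, then applies four stages of transformer blocks at widths `C,
2C, 4C, 8C`; a patch-merging layer after each stage halves every spatial
extent and doubles the width, ending in a `16C` bottleneck at 1/32 of the
input resolution.  Convolutional residual blocks (two bias-free 3x3x3
convolutions with non-affine instance normalization and leaky ReLU, plus a
projected identity) process the raw input and each encoder state onto the
skip paths; the decoder upsamples with transposed convolutions (kernel 2,
stride 2), concatenates the matching skip, and refines with the same
residual unit.  A 1x1x1 convolution produces the logits: three
sigmoid-gated overlapping region channels for the multi-modal brain MRI
task (whole tumor, tumor core, enhancing tumor), or 14 softmax classes
(13 organs plus background) for the abdominal CT task.

### The pooling token mixer

Inside each block the mixer computes, for every channel and voxel, the
plain average of the `K x K x K` neighborhood (stride 1).  The reference
formulation writes the operator over two in-plane indices; all feature
maps in this network are three-dimensional, so the same centered window is
applied along depth as well.  Two further choices are deliberate:

* **Border handling.**  Neighbors falling outside the volume are excluded
  from both the numerator and the denominator, so a constant field is an
  exact fixed point everywhere, including corners -- the operator "merely
  averages" and never dilutes borders with padding zeros.
* **Kernel size.**  No kernel size is fixed by the reference protocol;
  the default is `K = 3`, the smallest centered 3D neighborhood, exposed
  as `pool_kernel` in the configuration.
* **Identity subtraction.**  The PoolFormer lineage uses `pool(x) - x`
  inside the residual branch; the printed operator is plain averaging.
  Plain averaging is the default and `subtract_identity = TRUE` enables
  the variant.

The operator has no trainable parameters and linear cost in the number of
voxels, in contrast to the quadratic (per window) attention baseline.

### The attention baseline

The baseline mixer is 3D shifted-window attention: windows of width 7,
two blocks per stage alternating unshifted/shifted, heads `(3, 6, 12,
24)`, query scaling `1/sqrt(dim/heads)`, a learned relative-position-bias
table of `(2*7 - 1)^3` entries per head, and qkv biases.  Extents that are
not window multiples are padded and masked; extents smaller than the
window shrink the runtime window (the bias table keeps its configured
size, as in the reference implementations).

### Squeeze-and-excitation

The SE block squeezes each channel to its spatial mean, passes the
descriptor through a bottleneck (`channels/r`, rectifier) and an expansion
layer, and gates each channel with the logistic output in `(0, 1)`.
`use_se = TRUE` attaches one SE block after each of the five
convolutional encoder blocks and after each of the five decoder blocks.

## Parameter accounting as an architecture checksum

The package treats published trainable-parameter totals as architecture
checksums: `count_parameters()` enumerates the built parameter tree and
`architecture_checksum()` compares the totals (and the deltas between
configuration pairs) against the embedded reference table.  All 28
reference totals are reproduced exactly, which pins down several details
that prose descriptions leave open:

* Convolutional blocks use bias-free convolutions and *non-affine*
  instance norms; otherwise every total would be off by exactly `194 C`.
* The channel-configuration delta at `C = 48` (4,645 parameters between
  the 4-in/3-out and 1-in/14-out variants) is exactly the patch-embedding,
  first-encoder and output-head difference, confirming the decomposition.
* The SE increment (`182 C^2 + 50 C`; 106,032 at `C = 24`, 421,728 at
  `C = 48`) identifies the reduction ratio (4), the presence of both FC
  biases, and the placement: five encoder blocks at widths
  `(C, C, 2C, 4C, 16C)` and five decoder blocks at `(8C, 4C, 2C, C, C)` --
  the unique natural placement satisfying `sum(m) = 40`,
  `sum(m^2) = 364`.
* The attention-minus-pooling delta (`510 C^2 + 90 C`; 1,179,360 at
  `C = 48`) equals exactly the q/k/v projections (weights and biases) of
  all eight transformer blocks -- no block-subset swap can produce it,
  since the per-block quadratic coefficients are `4*4^i` and
  `sum 4^i = 127.5` would be required.  The pooling variant therefore
  retains each block's mixer *output projection* (used in the forward
  pass, after pooling) and its relative-position-bias table (allocated
  for drop-in weight-layout parity, unused by pooling).  `pool_proj` and
  `pool_bias_table` expose this: with both `FALSE` the block is the pure
  MetaFormer form whose mixer contributes zero parameters; with the
  defaults (`TRUE`) the built networks reproduce the reference totals.

```{r checksum}
tab <- rbind(count_grid(),  # 24 abdominal configurations
             count_grid(48L, in_channels = 4L, out_channels = 3L,
                        head = "sigmoid"))
architecture_checksum(tab)
```

## Losses and metrics

Training uses the soft Dice loss
`1 - 2*sum(p_i g_i) / (sum(p_i^2) + sum(g_i^2))`, computed per class and
averaged (all channels for the softmax head; the three overlapping region
channels for the sigmoid head).  The printed formula has no smoothing
term; a constant of `1e-5` is added to numerator and denominator to guard
the empty/empty case, with `smooth = 0` available for exact-formula
checks.  The Dice *score* operates on binarized masks (threshold 0.5 per
region, or channel argmax) and defines empty-vs-empty as 1.0 -- a
convention that must be picked and is configurable via `empty_value`.
Cross-validation tables aggregate as: per-class mean over folds, per-fold
mean over classes, and grand average = mean of the per-class averages.

## Synthetic phantoms

The generators exist so that every pipeline stage is testable without any
external download.  `generate_brain_phantom()` places three concentric
randomized ellipsoids (edema shell, necrotic shell, enhancing center)
inside a brain-shaped foreground, so the nested evaluation regions are
nonempty by construction, and renders four channels with distinct
per-tissue mean intensities plus Gaussian noise (default sd 0.05 on a
unit intensity scale).  `generate_abdomen_phantom()` places up to 13
pairwise-disjoint ellipsoidal blobs with distinct labels and intensities
inside a body-shaped foreground on one channel.  Contrasts are chosen so
each class is separable by a small model: the phantoms exercise geometry,
label structure, I/O and optimization, not imaging physics.  Passing
tests on phantoms therefore demonstrate that the architecture, losses and
pipeline are wired correctly -- not that real-data Dice levels are
attainable; real MRI/CT exhibit bias fields, anatomy, partial-volume
effects and inter-subject variability that the phantoms deliberately
omit.

## Numerical choices

* Normalization epsilons are `1e-5` (layer, instance).  A bottleneck with
  a single spatial voxel makes the non-affine instance norm collapse to
  zero (zero variance); regions of interest of at least `64` on one axis
  keep the deepest stage on the gradient path, and the connectivity test
  runs at `(64, 32, 32)` for exactly this reason.
* Initialization: truncated normal (sd 0.02, clipped at 2 sd) for
  transformer weights, fan-out-scaled normal for convolutions, zeros for
  biases; fully determined by the build seed.  Parameter counts never
  depend on the seed or the region of interest.
* Softmax rows are max-shifted before exponentiation; masked (shifted
  window) logits use an additive `-1e9`.
* GELU is the exact Gaussian form `x * pnorm(x)`.
* The optimizer is AdamW (decoupled weight decay `1e-5`), an extrapolation
  documented here because only the learning rate (1e-4) and batch size
  (1) are fixed by the reference protocol; a cosine schedule is optional.
* Argmax ties in label decisions resolve to the first (lowest) class.

## Problem sizes used by the test suite

The suite validates the full architecture at reduced scale, a deliberate
package choice so that every property is checkable on a single CPU:
`C = 12` networks on `32^3` patches for optimization tests (about two
seconds per step), `(64, 32, 32)` volumes for gradient-connectivity
audits, and exhaustive finite-difference checks on volumes of a few
hundred voxels.  The learnability smoke test trains `C = 12` pooling
networks for 200 steps at learning rate `3e-3` on one `32^3` phantom
whose extent equals the patch (every crop is the identity crop), reaching
a training soft Dice loss well below 0.2; at 1e-4 -- the rate appropriate
for hundreds of epochs on real data -- a 200-step run barely moves, so
the smoke configuration uses the larger rate.  Parameter accounting runs
at full scale (`C` up to 84) via shape-level builds that allocate no
weight values.

## Known limitations

* Batch size is fixed at 1 (the reference protocol's setting); there is
  no batching dimension.
* Training at published scale (128^3 patches, hundreds of epochs, real
  BraTS/BTCV volumes) is out of scope on CPU; published Dice scores are
  not reproducible at desk scale and are not targets of this package.
* The abdominal protocol's "96 x 96 input resolution" is read as a
  `96^3` 3D region of interest, since the network is inherently 3D and
  requires extents divisible by 32; a 2D slice reading would need a
  different architecture.
* Whether the deployed pooling mixer includes identity subtraction is not
  derivable from the parameter totals (both forms are parameter-free);
  the printed operator (plain averaging) is the default.
* The BraTS 2023 release renumbered the enhancing-tumor label in some
  distributions; the label map `{1, 2, 4}` is used as printed, and
  `brats_region_masks()` accepts a custom region/label mapping.

## Command-line interface

`inst/cli/poolunetr` is a thin Rscript wrapper with subcommands `synth`,
`folds`, `count-params`, `train`, `predict`, `evaluate`; `count-params
--check` exits nonzero on any checksum mismatch.  All subcommands thread
a single `--seed` through generation, splitting, initialization and
optimization.
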