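---
title: "CNN-Res methods: architecture, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CNN-Res methods: architecture, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the design decisions behind the package: how the
CNN-Res architecture is reconstructed from its published layer table, why
the block conventions are explicit objects, how the synthetic phantom is
designed, which numerical conventions are used and why, and what is out of
scope.

## 1. The architecture and its underdetermined internals

CNN-Res is specified publicly as a table of blocks with kernel sizes,
filter counts and output shapes: four encoder levels of
transition + residual blocks (filters 32, 64, 128, 256 doubling inside
each residual block), a bottleneck (5×5 transition to 512 at spatial size
5×5, residual to 1024, 1×1 compression to 64), and a decoder of 2×
nearest-neighbour upsampling, skip concatenation and 3×3 convolutions
ending in a 1×1 sigmoid head.

The table pins every output shape but leaves four block internals open.
The package reifies them as a `block_convention()`:

* **combine** — how a residual block merges its convolutional branch with
  the block input. Channel-wise *concatenation* is the only merge
  consistent with the table's channel doubling (an identity sum cannot
  change the channel count); a *projected add* (1×1 projection of the
  input to the doubled width, then addition) is the literal reading of a
  residual sum and is kept as an alternative.
* **width_factor** — the branch's 1×1 convolution width as a fraction of
  the block input channels.
* **compress_bn** — whether the bottleneck 1×1 compression keeps a batch
  normalisation.
* **conv_bias** — whether convolutions carry biases.

`reconcile_conventions()` enumerates
combine × width_factor {0.5, 1, 2} × compress_bn × conv_bias (24
conventions) and compares closed-form parameter budgets against the two
published totals.

**What reconciles.** The published 5,952 non-trainable parameters equal
2 running statistics × 2,976 normalised channels, which pins
`width_factor = 1` and `compress_bn = FALSE` (combine mode and biases do
not touch the normalisation schedule). The defaults additionally take
concatenation (forced by the shape table) and biased convolutions (the
common framework default).

**What does not.** No convention in the space reproduces the published
6,465,153 trainable parameters; the default convention yields 8,064,641.
The reconciliation report states each convention's totals and distances
rather than silently choosing one, and the test suite asserts the
discrepancy instead of papering over it. As a property substitute, the
framework count (summing allocated arrays) must equal the closed-form
count for every convention — `count_parameters()` errors on the first
mismatching layer.

The baseline U-Net is pinned to the classic topology (filter ladder
64–128–256–512 with a 1024 bridge, two biased 3×3 convolutions per level,
upsample + 2×2 convolution decoders, 2-filter penultimate and 1-filter
sigmoid output convolutions, no normalisation, dropout after encoder
level 4 and the bridge). This reproduces the published 31,031,685 total
exactly, with 0 non-trainable parameters.

## 2. Numerical engine

No deep-learning framework is assumed: the network is a static graph of
named nodes over (H, W, C, N) column-major arrays. Convolutions use an
im2col + GEMM kernel in C++ (Armadillo), stride 1 with "same" padding
(`pad_before = (k−1)/2`, the asymmetric remainder after). Gradients are
hand-written per operation and verified against central finite
differences through the whole graph (worst relative error observed:
3×10⁻⁸). Initialisation is He-normal (sd = √(2/fan-in)); optimisation is
Adam; dropout is inverted; batch normalisation follows the common
framework convention (ε = 10⁻³, running statistics with momentum 0.99 by
default) with train/eval modes.

## 3. Loss, metric and conventions

* **Soft Dice loss** `1 − (2Σtp + ε)/(Σt + Σp + ε)` with ε = 10⁻⁶; batch
  loss is the mean over images. Chosen over cross-entropy because lesions
  occupy a small fraction of each slice and Dice is the reported metric.
* **Binarisation** is strict: a pixel is lesion iff its probability is
  *greater than* the threshold (0.5 by default); a value exactly at the
  threshold maps to background.
* **Dice coefficient** of two binary masks is `2|A∩B|/(|A|+|B|)`; when
  both masks are empty it is defined as 1 (agreement on absence), when
  exactly one is empty it is 0.
* **Aggregation** — the headline number is the mean over 2-D slices;
  per-subject means are additionally reported because it is not stated
  whether published means are over slices or subjects.
* **Augmentation** — training uses the 8-element dihedral family
  ({identity, left–right flip} × {0°, 90°, 180°, 270°} counter-clockwise
  rotations), evaluation uses {identity, flip}; each evaluation variant is
  scored as an independent sample, which reproduces the published sample
  accounting. Transforms are pure index permutations (no interpolation).
* **Splits** are by subject (a seeded permutation partition), never by
  slice, so no subject leaks across partitions. The mini-batch size
  interpretation of the published "128" is batch size, and the published
  full-scale recipe (Adam, learning rate 10⁻⁴, batch 128, He-normal, L2 +
  dropout) is the `training_config()` default.
* **Brain centring** is per-slice by default (`per_slice = TRUE`), with a
  per-volume option, since the published pipeline does not state which;
  the choice is a flag, not a hidden constant.

## 4. The synthetic phantom

No clinical data ships with the package, so `generate_cohort()` draws a
cohort of paired DWI/FLAIR-like volumes with ground-truth masks:

* an elliptical "brain" of raised intensity with a random per-subject
  offset (exercises the brain-centring step);
* one ellipsoidal hyperintense lesion spanning a contiguous slice
  interval, with radii floored so every slice in the interval contains at
  least one lesion pixel (so lesion-slice selection is exact);
* modality contrast: the lesion is brighter on DWI than FLAIR (×1.0 vs
  ×0.6 of the contrast parameter), giving genuinely co-registered but
  non-identical modalities;
* smoothed uniform noise, and intensities snapped to float32 so NIfTI
  round-trips are lossless and byte-identical given a seed.

The phantom emulates the *contract* of the clinical data (hyperintense
lesion on a darker brain, two modalities, NIfTI volumes, per-subject
variability) — not its difficulty. It contains no skull, CSF, bilateral
intensity asymmetries, chronic lesions or imaging artefacts, so Dice
scores on it say nothing about clinical performance; they verify that the
implementation can learn.

## 5. Desk-scale problem sizes

The published experiments (160×160 inputs, 44 subjects, mini-batch 128,
GPU training) are far beyond a CPU test budget. The package therefore
defines its own desk-scale sizes, used by the examples and the
training-sanity tests: 9 subjects × 24 slices at 64×64, split 7/2 by
subject (~97 train / ~29 validation slices), a depth-2, 8-filter CNN-Res
(36,177 parameters), and `cnnres_desk_config()` (Adam 10⁻³, batch 8, ≤10
epochs). Two deliberate desk-scale deviations:

* **Batch-norm momentum 0.9** instead of 0.99: with only ~130 optimisation
  steps, running statistics at momentum 0.99 lag the batch statistics
  badly enough that evaluation-mode predictions collapse late in training;
  0.9 tracks them within the budget. Full-scale defaults are unchanged.
* **Overfit demonstrations use 2×2-grid-aligned targets.** The
  architecture ends in a 2× upsample followed by a 1×1 convolution, so
  its output is piecewise constant on 2×2 pixel blocks — a mask not
  aligned to that grid cannot be fitted below a structural loss floor
  (e.g. exactly 0.2 for a 4×4 lesion overlapping six rows of blocks).
  This is a faithful property of the published head, worth knowing when
  interpreting near-boundary errors at full scale too.

Under these conditions, held-out mean Dice reaches ≥ 0.80 in 3 of 3 tested
seeds (≈ 0.87/0.81/0.89), and a single aligned sample overfits to loss
< 10⁻³ within 200 steps.

## 6. Limitations

* The published clinical results (≈ 0.85 Dice locally, ≈ 0.79 on a public
  challenge cohort, ≈ 0.68 for the U-Net baseline, and second-scale
  prediction times) require the original private/clinical datasets and
  hardware; they are explicitly out of scope and are replaced by the
  architectural, accounting and training-sanity checks above.
* The published trainable parameter total is not reproducible from the
  public layer table under any enumerated convention (section 1); the
  package documents the discrepancy rather than resolving it.
* The engine is CPU-only and optimised for clarity and testability, not
  throughput; full-scale training is possible but slow.
* Only square single-channel inputs divisible by 2^(depth+1) are
  supported; multimodal fusion is by training on pooled slices, not by
  multi-channel input (the published pipeline also trains per-modality
  slices).
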