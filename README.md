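# cnnres

Builds, trains and evaluates **CNN-Res**, a U-shaped convolutional network
with pre-activation residual blocks, for binary segmentation of acute
ischemic stroke lesions on 2-D multimodal MRI slices (DWI and FLAIR). The
package is self-contained: it ships its own numerical engine (an
Rcpp/Armadillo im2col convolution core with hand-written backpropagation
and Adam), a synthetic MRI phantom generator so every example runs without
patient data, a pinned reference U-Net baseline, exact layer-by-layer
parameter accounting, and a command-line workflow.

## The science

Acute ischemic stroke lesions appear as hyperintense regions on
diffusion-weighted (DWI) and fluid-attenuated inversion recovery (FLAIR)
MRI. Manual delineation is slow and rater-dependent, so the segmentation
is posed as per-pixel binary classification of 2-D axial slices.

### Architecture

CNN-Res is an encoder–decoder ("U-shaped") network operating on
160×160×1 slices:

- **Encoder** — four repetitions of a *transition block* (3×3 convolution →
  batch normalisation → ReLU → 2×2 max-pool) followed by a *residual
  block* (BN → ReLU → 1×1 convolution → BN → ReLU → 3×3 convolution,
  combined with the block input). Filter counts double per level:
  32, 64, 128, 256.
- **Bottleneck** — a 5×5 transition to 512 channels at 5×5 spatial size, a
  residual block to 1024 channels, then a 1×1 *compression* convolution
  down to 64 channels.
- **Decoder** — four repetitions of 2× nearest-neighbour upsampling,
  channel-wise concatenation with the matching transition-block output
  (the skip connection), and a 3×3 convolution + ReLU; a final convolution
  to 32 channels, one last 2× upsample, and a 1×1 convolution with sigmoid
  producing a 160×160×1 probability map.

The residual rows of the architecture table leave four block internals
unspecified (how branch and input are merged, the 1×1 branch width,
whether the compression layer is normalised, whether convolutions carry
biases). These are reified as a `block_convention()` object;
`reconcile_conventions()` enumerates the 24-convention space and compares
each candidate's parameter budget with the published totals. Matching the
published **5,952 non-trainable parameters** (2,976 normalised channels ×
2 running statistics) pins width factor 1 and an unnormalised compression
layer; no convention in the space reproduces the published trainable
total, and the report quantifies each one's distance to it.

### Loss and metric

Training minimises the soft Dice loss over a predicted probability map
p and binary target t,

    L(t, p) = 1 − (2 Σᵢ tᵢ pᵢ + ε) / (Σᵢ tᵢ + Σᵢ pᵢ + ε),

with mini-batch loss the mean over images. Evaluation thresholds the
probabilities (strictly greater than 0.5) and scores each slice with the
Dice coefficient

    Dice(A, B) = 2|A ∩ B| / (|A| + |B|),

defined as 1 when both masks are empty and 0 when exactly one is.

### Data pipeline

Volumes are brain-centred (foreground centroid moved to the image
centre), restricted to lesion-bearing slices, resized to the model
resolution and min–max normalised to [0, 1]. Training augmentation is the
dihedral scheme — left–right flip × {0°, 90°, 180°, 270°} rotations, 8
samples per slice; evaluation augmentation is identity + flip, 2 samples
per slice. `augmentation_ledger()` reproduces the published sample
accounting exactly (560 → 4,480 train; 120 → 240 / 112 → 224 eval per
modality; 8,960 / 480 / 448 over two modalities; 275 × 8 × 2 = 4,400).

## Worked example

A desk-scale session on the synthetic cohort (9 subjects, 64×64 slices,
depth-2 model — one CPU, about half a minute). Outputs shown are the
actual printed results.

```r
library(cnnres)

params <- phantom_params(n_subjects = 9, slices_per_volume = 24,
                         height = 64, width = 64,
                         lesion_slice_range = c(12, 16), seed = 1001)
cohort <- generate_cohort(params)          # 18 volumes (9 subjects x DWI/FLAIR)

dwi <- Filter(function(v) v$modality == "DWI", cohort)
split <- split_by_subject(vapply(dwi, function(v) v$subject_id, character(1)),
                          counts = c(7, 2, 0), seed = 1)
prep <- function(ids) unlist(lapply(
  Filter(function(v) v$subject_id %in% ids, dwi),
  prepare_volume, size = 64), recursive = FALSE)
train_slices <- prep(split$train)          # 97 slices
val_slices   <- prep(split$val)            # 29 slices

model <- build_cnnres(block_convention(bn_momentum = 0.9),
                      input_size = 64, depth = 2, base_filters = 8)
model
#> <seg_network> cnnres, input 64x64x1
#>   layers: 50   parameters: 36,177 (35,841 trainable, 336 non-trainable)

fit <- train_model(model, train_slices, val_slices, cnnres_desk_config(seed = 1))
fit
#> <seg_fit> cnnres, 10 epochs
#>   final train loss 0.1490; best val dice 0.8701 (epoch 10)

glance(fit)
#> # A tibble: 1 × 5
#>   epochs final_train_loss best_val_dice best_epoch n_parameters
#>    <int>            <dbl>         <dbl>      <int>        <dbl>
#> 1     10            0.149         0.870         10        36177

rpt <- evaluate_model(fit, val_slices)
summary(rpt)
#> # A tibble: 1 × 3
#>       n mean_dice sd_dice
#>   <int>     <dbl>   <dbl>
#> 1    29     0.870  0.0633
summary(rpt, by = "subject")
#> # A tibble: 2 × 3
#>   subject n_slices mean_dice
#>   <chr>      <int>     <dbl>
#> 1 sub05         14     0.867
#> 2 sub08         15     0.873
```

With evaluation-time flip augmentation (each slice scored twice) the mean
Dice is 0.8679 over 58 samples. `tidy(fit)` returns the per-epoch history
and `autoplot(fit)` / `autoplot(rpt)` draw the training curves and the
per-subject Dice distribution.

The full-size model and baseline:

```r
count_parameters(build_cnnres())
#> Parameters: total 8,070,593
#>   trainable:     8,064,641
#>   non-trainable: 5,952
count_parameters(build_unet_baseline())
#> Parameters: total 31,031,685
#>   trainable:     31,031,685
#>   non-trainable: 0
reconcile_conventions()   # 24-convention parameter-budget reconciliation
```

## Command line

A thin wrapper over the same functions is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "cnnres", package = "cnnres"))')
$CLI synth      --out raw --subjects 9 --seed 1001 --size 64 --slices 24
$CLI preprocess --in raw --out prep --size 64
$CLI augment    --in prep --out aug --mode train
$CLI summary    --arch cnnres
$CLI reconcile
```

Every stage writes a run manifest (config, seed, md5 of each artifact)
next to its outputs.

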