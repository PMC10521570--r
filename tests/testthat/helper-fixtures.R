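# Shared small fixtures, built in code.

# Tiny cohort parameters: fast to generate, still exercises every contract.
tiny_params <- function(...) {
  defaults <- list(n_subjects = 3L, slices_per_volume = 12L, height = 32L,
                   width = 32L, lesion_slice_range = c(4L, 8L),
                   lesion_radius_range = c(3, 6), seed = 11L)
  do.call(phantom_params, utils::modifyList(defaults, list(...)))
}

# Desk-scale cohort + model sizes used by the training sanity checks.
desk_cohort_params <- function(seed) {
  phantom_params(n_subjects = 9L, slices_per_volume = 24L, height = 64L,
                 width = 64L, lesion_slice_range = c(12L, 16L), seed = seed)
}

desk_model <- function(bn_momentum = 0.9) {
  build_cnnres(block_convention(bn_momentum = bn_momentum), input_size = 64L,
               depth = 2L, base_filters = 8L)
}

# Prepared model-space slices for the subjects in `ids`, one modality.
prepare_subjects <- function(cohort, ids, modality = "DWI", size = 64L) {
  keep <- Filter(function(v) v$modality == modality && v$subject_id %in% ids,
                 cohort)
  unlist(lapply(keep, prepare_volume, size = size), recursive = FALSE)
}

# Frozen output schedule of the full-size architecture (H, W, C per block).
cnnres_reference_schedule <- function() {
  tibble::tribble(
    ~label,                    ~out_h, ~out_w, ~out_c,
    "Transition Block 1",          80L,    80L,    32L,
    "Residual Block 1",            80L,    80L,    64L,
    "Transition Block 2",          40L,    40L,    64L,
    "Residual Block 2",            40L,    40L,   128L,
    "Transition Block 3",          20L,    20L,   128L,
    "Residual Block 3",            20L,    20L,   256L,
    "Transition Block 4",          10L,    10L,   256L,
    "Residual Block 4",            10L,    10L,   512L,
    "Bottleneck (transition)",      5L,     5L,   512L,
    "Bottleneck (residual)",        5L,     5L,  1024L,
    "Bottleneck (compress)",        5L,     5L,    64L,
    "Upsampling 1",                10L,    10L,    64L,
    "Concatenate 1",               10L,    10L,   320L,
    "Conv 1",                      10L,    10L,   256L,
    "Upsampling 2",                20L,    20L,   256L,
    "Concatenate 2",               20L,    20L,   384L,
    "Conv 2",                      20L,    20L,   128L,
    "Upsampling 3",                40L,    40L,   128L,
    "Concatenate 3",               40L,    40L,   192L,
    "Conv 3",                      40L,    40L,    64L,
    "Upsampling 4",                80L,    80L,    64L,
    "Concatenate 4",               80L,    80L,    96L,
    "Conv 4",                      80L,    80L,    64L,
    "Conv 5",                      80L,    80L,    32L,
    "Upsampling 5",               160L,   160L,    32L,
    "Output",                     160L,   160L,     1L)
}

# One-sample overfitting fixture. The network ends in a 2x nearest-neighbour
# upsample followed by a 1x1 convolution, so its output is piecewise
# constant on 2x2 blocks; the lesion is placed on that grid (odd start
# rows/columns) so the target is exactly representable.
overfit_fixture <- function(size = 16L) {
  set.seed(70)
  msk <- matrix(0, size, size)
  msk[5:8, 7:10] <- 1
  img <- 0.2 + 0.6 * msk + matrix(runif(size^2, 0, 0.1), size, size)
  list(slice_pair(img / max(img), msk, "s1", "DWI", 1L))
}

# A deterministic asymmetric slice_pair (no dihedral symmetry).
asym_slice <- function(n = 6L) {
  img <- matrix(seq_len(n * n), n, n) / (n * n)
  msk <- matrix(0, n, n); msk[2L, 3L] <- 1; msk[2L, 4L] <- 1
  slice_pair(img, msk, "subA", "DWI", 1L)
}
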