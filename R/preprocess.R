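# Two-stage slice preparation: (1) centre the brain object in every slice,
# (2) keep only lesion-bearing slices, resample to the model resolution and
# min-max normalise. Splitting is always by subject, never by slice, so no
# subject contributes to more than one partition.

#' A prepared 2-D slice with its mask and provenance
#'
#' @param image numeric matrix.
#' @param mask binary matrix, same shape.
#' @param subject_id,modality,slice_index provenance.
#' @param transform_id augmentation tag (`"identity"` until augmented).
#' @return a `slice_pair`.
#' @export
slice_pair <- function(image, mask, subject_id, modality, slice_index,
                       transform_id = "identity") {
  if (!identical(dim(image), dim(mask)))
    stop("image and mask shapes differ")
  if (!all(mask %in% c(0, 1))) stop("mask values must be 0/1")
  if (any(!is.finite(image))) stop("image contains non-finite values")
  structure(list(image = image, mask = mask,
                 subject_id = as.character(subject_id),
                 modality = as.character(modality),
                 slice_index = as.integer(slice_index),
                 transform_id = as.character(transform_id)),
            class = "slice_pair")
}

#' Centre the bright object in a slice
#'
#' Pixels above `threshold_frac` of the slice maximum are taken as
#' foreground; the slice content is translated (whole pixels, zero fill) so
#' the foreground centroid lands on the geometric image centre. An
#' all-background slice is returned unchanged.
#'
#' @param slice_image numeric matrix.
#' @param threshold_frac foreground threshold as a fraction of the maximum.
#' @return the shifted matrix.
#' @export
center_brain <- function(slice_image, threshold_frac = 0.1) {
  stopifnot(is.matrix(slice_image), length(slice_image) > 0)
  shift <- center_shift(slice_image, threshold_frac)
  if (all(shift == 0L)) return(slice_image)
  translate_zero(slice_image, shift)
}

# Integer (row, col) shift that centres the foreground centroid; c(0, 0)
# for an all-background slice.
center_shift <- function(slice_image, threshold_frac = 0.1) {
  mx <- max(slice_image)
  fg <- which(slice_image > threshold_frac * mx, arr.ind = TRUE)
  if (nrow(fg) == 0L || mx <= 0) return(c(0L, 0L))
  centroid <- colMeans(fg)
  center <- (dim(slice_image) + 1) / 2
  as.integer(round(center - centroid))
}

translate_zero <- function(m, shift) {
  out <- matrix(0, nrow(m), ncol(m))
  src_r <- seq_len(nrow(m)) - shift[1L]
  src_c <- seq_len(ncol(m)) - shift[2L]
  ok_r <- src_r >= 1L & src_r <= nrow(m)
  ok_c <- src_c >= 1L & src_c <= ncol(m)
  out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' Centre every slice of a subject volume
#'
#' The same shift is applied to the image and the mask of each slice so
#' the two stay aligned. With `per_slice = FALSE` a single shift — computed
#' from the mid-stack slice — is applied to all slices.
#'
#' @param volume a [subject_volume()].
#' @param per_slice logical; per-slice centering is the default.
#' @param threshold_frac see [center_brain()].
#' @return a centred `subject_volume`.
#' @export
center_volume <- function(volume, per_slice = TRUE, threshold_frac = 0.1) {
  d <- dim(volume$image)
  img <- volume$image; msk <- volume$mask
  global_shift <- if (!per_slice)
    center_shift(img[, , ceiling(d[3L] / 2)], threshold_frac)
  for (z in seq_len(d[3L])) {
    shift <- if (per_slice) center_shift(img[, , z], threshold_frac)
             else global_shift
    if (all(shift == 0L)) next
    img[, , z] <- translate_zero(img[, , z], shift)
    msk[, , z] <- translate_zero(msk[, , z], shift)
  }
  subject_volume(img, msk, volume$subject_id, volume$modality)
}

#' Select the lesion-bearing slices of a volume
#'
#' Returns exactly the slices whose mask has at least one positive pixel,
#' in ascending slice order, as (pre-resize) [slice_pair()] objects.
#'
#' @param volume a [subject_volume()].
#' @return list of `slice_pair` (possibly empty).
#' @export
select_lesion_slices <- function(volume) {
  if (!identical(dim(volume$image), dim(volume$mask)))
    stop("image and mask dimensions differ")
  pos <- which(apply(volume$mask, 3L, sum) > 0)
  lapply(pos, function(z)
    slice_pair(volume$image[, , z], volume$mask[, , z], volume$subject_id,
               volume$modality, z))
}

#' Resample and normalise a slice to model space
#'
#' The image is resampled to `size` x `size` with bilinear interpolation and
#' min-max normalised to \[0, 1\] per slice; the mask is resampled with
#' nearest-neighbour so it stays binary. A constant-intensity image
#' normalises to all zeros.
#'
#' @param slice a [slice_pair()].
#' @param size target side length (default 160).
#' @return a `slice_pair` in model space.
#' @export
to_model_space <- function(slice, size = 160L) {
  img <- slice$image; msk <- slice$mask
  if (!all(dim(img) == c(size, size))) {
    img <- EBImage::resize(img, w = size, h = size, filter = "bilinear")
    msk <- EBImage::resize(msk, w = size, h = size, filter = "none")
    msk <- (msk > 0.5) + 0
  }
  rng <- range(img)
  img <- if (diff(rng) == 0) matrix(0, size, size)
         else (img - rng[1L]) / diff(rng)
  slice_pair(img, msk, slice$subject_id, slice$modality, slice$slice_index,
             slice$transform_id)
}

#' Full slice preparation for one volume
#'
#' Centre (optional), select lesion slices, resample and normalise.
#'
#' @param volume a [subject_volume()].
#' @param size model-space side length.
#' @param center centre the brain first.
#' @param per_slice see [center_volume()].
#' @return list of model-space `slice_pair` objects.
#' @export
prepare_volume <- function(volume, size = 160L, center = TRUE,
                           per_slice = TRUE) {
  if (center) volume <- center_volume(volume, per_slice = per_slice)
  lapply(select_lesion_slices(volume), to_model_space, size = size)
}

#' Split subjects into train / validation / test partitions
#'
#' A seeded random permutation of the subject ids is partitioned by
#' `counts`; every slice of a subject therefore lands in exactly one
#' partition.
#'
#' @param subject_ids character vector of unique subject ids.
#' @param counts integer vector `c(train, val, test)` summing to
#'   `length(subject_ids)`.
#' @param seed integer seed.
#' @return a `dataset_split`: list with `train`, `val`, `test`.
#' @export
split_by_subject <- function(subject_ids, counts = c(34L, 5L, 5L), seed = 1L) {
  subject_ids <- unique(as.character(subject_ids))
  if (sum(counts) != length(subject_ids))
    stop("counts sum to ", sum(counts), " but there are ",
         length(subject_ids), " subjects")
  perm <- withr::with_seed(seed, sample(subject_ids))
  structure(list(train = perm[seq_len(counts[1L])],
                 val = perm[counts[1L] + seq_len(counts[2L])],
                 test = perm[counts[1L] + counts[2L] + seq_len(counts[3L])]),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train %d / val %d / test %d subjects\n",
              length(x$train), length(x$val), length(x$test)))
  invisible(x)
}
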