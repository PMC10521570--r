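# Dihedral augmentation of square slices.
#
# Training expands every slice into 8 samples: the four quarter-turn
# rotations of the original, then the four rotations of its mirror image —
# the full symmetry group of the square. Evaluation uses only the identity
# and the mirror (2 samples per slice). All transforms are pure index
# permutations: no interpolation, and the pixel multiset is preserved, so a
# mask stays binary and its lesion pixel count is invariant.

#' Augmentation policy
#'
#' @param mode `"train"` (8 transforms: \{no-flip, flip\} x \{0, 90, 180,
#'   270\} degrees) or `"eval"` (2 transforms: identity and flip).
#' @return an `augmentation_policy` with a `transforms` data frame
#'   (`flip`, `quarter_turns`).
#' @export
augmentation_policy <- function(mode = c("train", "eval")) {
  mode <- match.arg(mode)
  transforms <- if (mode == "train")
    expand.grid(quarter_turns = 0:3, flip = c(FALSE, TRUE))[, 2:1]
  else data.frame(flip = c(FALSE, TRUE), quarter_turns = c(0L, 0L))
  structure(list(mode = mode, transforms = transforms),
            class = "augmentation_policy")
}

rot90_ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]

flip_lr <- function(m) m[, ncol(m):1, drop = FALSE]

#' Apply one dihedral transform to a slice
#'
#' Mirrors left-right first (if `flip`), then rotates counter-clockwise by
#' `quarter_turns` x 90 degrees; the identical index permutation is applied
#' to the image and the mask, and the transform is recorded in
#' `transform_id` (e.g. `"f1r2"`).
#'
#' @param slice a [slice_pair()] with square image.
#' @param flip logical.
#' @param quarter_turns integer 0-3.
#' @return the transformed `slice_pair`.
#' @export
apply_transform <- function(slice, flip = FALSE, quarter_turns = 0L) {
  img <- slice$image
  if (nrow(img) != ncol(img))
    stop("dihedral transforms require a square slice; got ",
         nrow(img), "x", ncol(img))
  quarter_turns <- as.integer(quarter_turns) %% 4L
  msk <- slice$mask
  if (flip) { img <- flip_lr(img); msk <- flip_lr(msk) }
  for (i in seq_len(quarter_turns)) { img <- rot90_ccw(img); msk <- rot90_ccw(msk) }
  tid <- sprintf("f%dr%d", as.integer(flip), quarter_turns)
  if (!identical(slice$transform_id, "identity"))
    tid <- paste(slice$transform_id, tid, sep = "+")
  slice_pair(img, msk, slice$subject_id, slice$modality, slice$slice_index,
             tid)
}

#' Augment a slice set under a policy
#'
#' Output order is all transforms of slice 1, then all transforms of slice
#' 2, and so on; output length is `length(slices) * nrow(policy$transforms)`.
#'
#' @param slices list of `slice_pair` objects (possibly empty).
#' @param policy an [augmentation_policy()].
#' @return list of transformed `slice_pair` objects.
#' @export
augment <- function(slices, policy = augmentation_policy("train")) {
  stopifnot(inherits(policy, "augmentation_policy"))
  tf <- policy$transforms
  out <- vector("list", length(slices) * nrow(tf))
  k <- 0L
  for (s in slices) {
    for (i in seq_len(nrow(tf))) {
      k <- k + 1L
      out[[k]] <- apply_transform(s, tf$flip[i], tf$quarter_turns[i])
    }
  }
  out
}

#' Sample-accounting table for an augmentation plan
#'
#' Multiplies per-partition slice counts by the policy sizes (8 for
#' training, 2 for evaluation) and totals across modalities.
#'
#' @param train,val,test slice counts per modality before augmentation.
#' @param n_modalities number of modalities.
#' @return a tibble with per-modality and total augmented counts.
#' @export
augmentation_ledger <- function(train, val, test, n_modalities = 2L) {
  n_train <- nrow(augmentation_policy("train")$transforms)
  n_eval <- nrow(augmentation_policy("eval")$transforms)
  tibble::tibble(
    partition = c("train", "val", "test"),
    slices = c(train, val, test),
    factor = c(n_train, n_eval, n_eval),
    augmented = c(train * n_train, val * n_eval, test * n_eval),
    total_all_modalities = n_modalities * c(train * n_train, val * n_eval,
                                            test * n_eval))
}
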