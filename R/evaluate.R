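# Dice-coefficient evaluation: thresholding of probability maps, per-slice
# overlap scores, and aggregated reports (slice-level and subject-level,
# with and without the evaluation-time flip augmentation).

#' Threshold a probability map
#'
#' @param probability_map array of values in \[0, 1\].
#' @param threshold strict cut: pixels become 1 where value > threshold
#'   (a value exactly at the threshold maps to 0).
#' @return binary array of the same shape.
#' @export
binarize <- function(probability_map, threshold = 0.5) {
  if (any(probability_map < 0 | probability_map > 1))
    stop("probability map contains values outside [0, 1]")
  out <- (probability_map > threshold) + 0
  if (!is.null(dim(probability_map))) dim(out) <- dim(probability_map)
  out
}

#' Dice similarity coefficient of two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`. When both masks are empty the score is
#' defined as 1 (perfect agreement on the absence of lesion); when exactly
#' one is empty it is 0.
#'
#' @param y,y_hat same-shape binary arrays.
#' @return scalar in \[0, 1\].
#' @export
dice_coefficient <- function(y, y_hat) {
  if (length(y) != length(y_hat) ||
      (!is.null(dim(y)) && !is.null(dim(y_hat)) &&
       !identical(dim(y), dim(y_hat))))
    stop("mask shapes differ")
  if (!all(y %in% c(0, 1)) || !all(y_hat %in% c(0, 1)))
    stop("dice_coefficient expects binary masks")
  sy <- sum(y); sh <- sum(y_hat)
  if (sy + sh == 0) return(1)
  2 * sum(y * y_hat) / (sy + sh)
}

#' Evaluate a model on a slice set
#'
#' Predicts every slice, thresholds at `threshold`, and scores each
#' prediction against its mask with the Dice coefficient. With
#' `flip_augment = TRUE` the evaluation-time augmentation is applied first,
#' so each slice contributes two evaluation samples (identity and mirrored),
#' matching the published sample accounting; each variant is scored as an
#' independent sample.
#'
#' @param model a `seg_fit`, `seg_network`, or a function mapping an
#'   (H, W, 1, N) image array to same-shape probability maps (useful for
#'   oracle or baseline predictors).
#' @param slices non-empty list of `slice_pair` objects.
#' @param threshold binarisation threshold.
#' @param flip_augment evaluate on flip-augmented samples as well.
#' @return a `dice_report`: tibble with one row per evaluated sample
#'   (subject, modality, slice index, transform, dice) and attributes
#'   `threshold` and `mean_dice`.
#' @export
evaluate_model <- function(model, slices, threshold = 0.5,
                           flip_augment = FALSE) {
  if (length(slices) == 0L) stop("empty evaluation set")
  if (flip_augment) slices <- augment(slices, augmentation_policy("eval"))
  st <- stack_slices(slices)
  probs <- if (is.function(model)) model(st$image) else
    predict(model, st$image)
  n <- length(slices)
  dice <- vapply(seq_len(n), function(i)
    dice_coefficient(st$mask[, , 1L, i],
                     binarize(probs[, , 1L, i], threshold)), numeric(1))
  rpt <- tibble::tibble(
    subject = vapply(slices, function(s) s$subject_id, character(1)),
    modality = vapply(slices, function(s) s$modality, character(1)),
    slice_index = vapply(slices, function(s) as.integer(s$slice_index),
                         integer(1)),
    transform = vapply(slices, function(s) s$transform_id, character(1)),
    dice = dice)
  attr(rpt, "threshold") <- threshold
  attr(rpt, "mean_dice") <- mean(dice)
  class(rpt) <- c("dice_report", class(rpt))
  rpt
}

#' Summarise a Dice report
#'
#' @param object a `dice_report`.
#' @param by `"slice"` for the overall slice-level mean, `"subject"` for
#'   per-subject means (each subject's slices averaged first).
#' @param ... unused.
#' @return a tibble.
#' @export
summary.dice_report <- function(object, by = c("slice", "subject"), ...) {
  by <- match.arg(by)
  if (by == "slice") {
    tibble::tibble(n = nrow(object), mean_dice = mean(object$dice),
                   sd_dice = stats::sd(object$dice))
  } else {
    means <- tapply(object$dice, object$subject, mean)
    tibble::tibble(subject = names(means), n_slices = as.integer(
      table(object$subject)[names(means)]), mean_dice = as.numeric(means))
  }
}

#' @export
print.dice_report <- function(x, ...) {
  cat(sprintf("<dice_report> %d samples, threshold %.2f, mean Dice %.4f\n",
              nrow(x), attr(x, "threshold"), attr(x, "mean_dice")))
  NextMethod()
}

#' Write a Dice report to disk
#'
#' Emits a tab-delimited per-slice table and a JSON summary (slice-level and
#' subject-level means) side by side.
#'
#' @param report a `dice_report`.
#' @param path output path stem; `<path>.tsv` and `<path>.json` are written.
#' @return invisibly, the two paths.
#' @export
write_dice_report <- function(report, path) {
  tsv <- paste0(path, ".tsv"); js <- paste0(path, ".json")
  utils::write.table(as.data.frame(report), tsv, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(
    threshold = attr(report, "threshold"),
    n = nrow(report),
    mean_dice_slices = mean(report$dice),
    mean_dice_subjects = mean(summary(report, by = "subject")$mean_dice),
    per_subject = summary(report, by = "subject")), js,
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(tsv, js))
}
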