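# Lesion-focused training objective: per-image soft Dice.
#
# Stroke lesions occupy a small fraction of each slice, so a pixelwise
# cross-entropy is dominated by the background class; the soft Dice loss
# scores the overlap of the predicted probability mass with the lesion
# directly and is insensitive to the background volume.

#' Soft Dice loss for one image
#'
#' `1 - (2 * sum(t*p) + eps) / (sum(t) + sum(p) + eps)`. The smoothing term
#' `eps` keeps the loss defined (and zero) when both the mask and the
#' prediction are empty.
#'
#' @param true_mask binary array/matrix.
#' @param predicted_map same-shape array of probabilities in \[0, 1\].
#' @param eps smoothing constant, > 0.
#' @return scalar loss in \[0, 1\].
#' @export
soft_dice_loss <- function(true_mask, predicted_map, eps = 1e-6) {
  if (length(true_mask) != length(predicted_map) ||
      (!is.null(dim(true_mask)) && !is.null(dim(predicted_map)) &&
       !identical(dim(true_mask), dim(predicted_map))))
    stop("true_mask and predicted_map shapes differ")
  stopifnot(eps > 0)
  t <- as.numeric(true_mask); p <- as.numeric(predicted_map)
  1 - (2 * sum(t * p) + eps) / (sum(t) + sum(p) + eps)
}

# Gradient of soft_dice_loss w.r.t. the prediction, same shape as p.
soft_dice_loss_grad <- function(true_mask, predicted_map, eps = 1e-6) {
  t <- as.numeric(true_mask); p <- as.numeric(predicted_map)
  num <- 2 * sum(t * p) + eps
  den <- sum(t) + sum(p) + eps
  g <- -(2 * t * den - num) / den^2
  if (!is.null(dim(predicted_map))) dim(g) <- dim(predicted_map)
  g
}

#' Mean soft Dice loss over a batch
#'
#' @param TX list (or (H, W, 1, N) array) of true masks.
#' @param PY list (or same-shape array) of predicted probability maps.
#' @param eps smoothing constant.
#' @return scalar: the arithmetic mean of the per-image losses.
#' @export
batch_loss <- function(TX, PY, eps = 1e-6) {
  TX <- as_image_list(TX); PY <- as_image_list(PY)
  if (length(TX) != length(PY)) stop("TX and PY lengths differ")
  if (length(TX) == 0L) stop("empty batch")
  mean(mapply(soft_dice_loss, TX, PY, MoreArgs = list(eps = eps)))
}

# Gradient of batch_loss w.r.t. the stacked predictions (H, W, 1, N).
batch_loss_grad <- function(tx, py, eps = 1e-6) {
  n <- dim(py)[4L]
  g <- array(0, dim(py))
  for (i in seq_len(n))
    g[, , , i] <- soft_dice_loss_grad(tx[, , , i], py[, , , i], eps) / n
  g
}

as_image_list <- function(x) {
  if (is.list(x)) return(x)
  if (is.array(x) && length(dim(x)) == 4L)
    return(lapply(seq_len(dim(x)[4L]), function(i) x[, , , i]))
  if (is.array(x) && length(dim(x)) == 3L)
    return(lapply(seq_len(dim(x)[3L]), function(i) x[, , i]))
  list(x)
}
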