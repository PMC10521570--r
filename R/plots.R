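# Tidiers and plots for fitted models and reports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history of a fit
#'
#' @param x a `seg_fit`.
#' @param ... unused.
#' @return tibble with `epoch`, `train_loss`, `val_loss`, `val_dice`.
#' @export
tidy.seg_fit <- function(x, ...) x$history

#' One-row summary of a fit
#'
#' @param x a `seg_fit`.
#' @param ... unused.
#' @return tibble with the final train loss, best validation Dice and its
#'   epoch, epoch count and parameter total.
#' @export
glance.seg_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs = nrow(h),
    final_train_loss = h$train_loss[nrow(h)],
    best_val_dice = if (all(is.na(h$val_dice))) NA_real_
                    else max(h$val_dice, na.rm = TRUE),
    best_epoch = x$best_epoch,
    n_parameters = count_parameters(x$model)$total)
}

#' Training-history curves
#'
#' @param object a `seg_fit`.
#' @param ... unused.
#' @return a ggplot: loss curves and validation Dice per epoch.
#' @export
autoplot.seg_fit <- function(object, ...) {
  h <- object$history
  long <- rbind(
    data.frame(epoch = h$epoch, metric = "train loss", value = h$train_loss),
    data.frame(epoch = h$epoch, metric = "val loss", value = h$val_loss),
    data.frame(epoch = h$epoch, metric = "val dice", value = h$val_dice))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Per-subject Dice distribution
#'
#' @param object a `dice_report`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.dice_report <- function(object, ...) {
  df <- as.data.frame(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subject, y = .data$dice)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = mean(df$dice), linetype = 2) +
    ggplot2::labs(x = "subject", y = "Dice coefficient") +
    ggplot2::ylim(0, 1) + ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot

#' Show a slice with its mask (and optionally a prediction) side by side
#'
#' @param slice a `slice_pair`.
#' @param prediction optional probability map matrix.
#' @return a ggplot raster panel.
#' @export
plot_slice_pair <- function(slice, prediction = NULL) {
  panel <- function(m, what) {
    d <- dim(m)
    data.frame(row = rep(seq_len(d[1L]), d[2L]),
               col = rep(seq_len(d[2L]), each = d[1L]),
               value = as.vector(m), panel = what)
  }
  df <- rbind(panel(slice$image, "image"), panel(slice$mask, "mask"))
  if (!is.null(prediction)) df <- rbind(df, panel(prediction, "prediction"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() + ggplot2::theme_void() +
    ggplot2::labs(fill = NULL,
                  title = sprintf("%s / %s / slice %d", slice$subject_id,
                                  slice$modality, slice$slice_index))
}
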