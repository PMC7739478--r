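# broom-style tidiers and ggplot2 autoplot methods.

#' Tidy a training run
#'
#' @param x a `ptx_training` from [train()].
#' @param ... unused.
#' @return the per-epoch history tibble.
#' @export
tidy.ptx_training <- function(x, ...) x$history

#' @rdname tidy.ptx_training
#' @export
glance.ptx_training <- function(x, ...) {
  tibble(epochs_run = x$stopped_epoch,
         best_epoch = x$best_epoch,
         best_val_dsc1 = x$best_val_dsc1,
         final_loss = x$history$loss[nrow(x$history)],
         loss_mode = x$config$loss_mode)
}

#' Tidy an evaluation
#'
#' @param x a `ptx_evaluation` from [evaluate()].
#' @param ... unused.
#' @return `tidy()`: the per-image report tibble; `glance()`: a one-row
#'   summary.
#' @export
tidy.ptx_evaluation <- function(x, ...) x$per_image

#' @rdname tidy.ptx_evaluation
#' @export
glance.ptx_evaluation <- function(x, ...) {
  s <- x$summary
  tibble(n = s$n, mpa = s$mpa, pa1 = s$pa1, dsc = s$dsc, dsc1 = s$dsc1,
         hd_mean = s$hd_mean, hd_max = s$hd_max,
         accuracy = s$diagnostics$accuracy,
         sensitivity = s$diagnostics$sensitivity,
         specificity = s$diagnostics$specificity,
         ppv = s$diagnostics$ppv, npv = s$diagnostics$npv,
         f1 = s$diagnostics$f1)
}

#' Plot a training run
#'
#' Loss and validation DSC1 per epoch, with the best epoch marked.
#'
#' @param object a `ptx_training`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ptx_training <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history[c("epoch", "loss", "val_dsc1")],
                           -"epoch", names_to = "metric")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Training loss and validation DSC1") +
    ggplot2::theme_minimal()
}

#' Plot an evaluation
#'
#' Histogram of per-image lesion Dice scores, split by true image label.
#'
#' @param object a `ptx_evaluation`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ptx_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$per_image,
                  ggplot2::aes(x = .data$dsc1, fill = .data$label)) +
    ggplot2::geom_histogram(bins = 20, position = "stack") +
    ggplot2::labs(x = "per-image DSC1", y = "images",
                  title = "Segmentation quality distribution") +
    ggplot2::theme_minimal()
}

#' Display a phantom with its mask outline
#'
#' @param phantom a [generate_phantom()] result.
#' @return a ggplot object (image raster with the lesion contour
#'   overlaid).
#' @export
plot_phantom <- function(phantom) {
  img <- phantom$image
  df <- tibble(row = as.vector(row(img)), col = as.vector(col(img)),
               value = as.vector(img))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, title = phantom$label) +
    ggplot2::theme_void()
  b <- detect_boundary(phantom$mask)
  if (any(b)) {
    bd <- which(b, arr.ind = TRUE)
    p <- p + ggplot2::geom_point(
      data = tibble(row = bd[, 1], col = bd[, 2]),
      colour = "red", size = 0.3)
  }
  p
}
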