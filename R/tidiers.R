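#' Tidy the training history of an OCunet fit
#'
#' @param x An `ocunet_fit`.
#' @param ... Unused.
#' @return Tibble with columns `epoch`, `loss`, `lr`, `val_dice`.
#' @export
tidy.ocunet_fit <- function(x, ...) {
  tibble::as_tibble(x$log)
}

#' One-row summary of an OCunet fit
#'
#' @param x An `ocunet_fit`.
#' @param ... Unused.
#' @return Tibble with `epochs`, `final_loss`, `best_val_dice`,
#'   `best_epoch`, `n_params`, `seed`.
#' @export
glance.ocunet_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$log),
                 final_loss = tail(x$log$loss, 1),
                 best_val_dice = x$best_val_dice,
                 best_epoch = x$best_epoch,
                 n_params = .ocunet_n_params(x$params),
                 seed = x$seed)
}

#' Plot the training history of an OCunet fit
#'
#' Training loss per epoch with held-out Dice overlaid at the epochs
#' where validation ran.
#'
#' @param object An `ocunet_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ocunet_fit <- function(object, ...) {
  log <- tibble::as_tibble(object$log)
  p <- ggplot2::ggplot(log, ggplot2::aes(x = .data$epoch)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$loss, colour = "training loss")) +
    ggplot2::labs(x = "epoch", y = "value", colour = NULL) +
    ggplot2::theme_minimal()
  vd <- log[!is.na(log$val_dice), ]
  if (nrow(vd) > 0)
    p <- p + ggplot2::geom_point(data = vd,
                                 ggplot2::aes(y = .data$val_dice, colour = "held-out Dice")) +
      ggplot2::geom_line(data = vd,
                         ggplot2::aes(y = .data$val_dice, colour = "held-out Dice"),
                         linetype = "dashed")
  p
}

#' Plot a 2-D slice of a volume with optional mask overlays
#'
#' @param volume A [seg_volume()] or 2-D/3-D array.
#' @param mask,pred Optional reference / predicted binary masks.
#' @param slice Index along the last axis for 3-D input.
#' @return A ggplot object.
#' @export
plot_slice <- function(volume, mask = NULL, pred = NULL, slice = 1L) {
  take <- function(v) {
    a <- if (inherits(v, "seg_volume")) v$voxels else v
    if (length(dim(a)) == 3L) a <- a[, , slice]
    a
  }
  v <- take(volume)
  df <- expand.grid(x = seq_len(nrow(v)), y = seq_len(ncol(v)))
  df$intensity <- as.vector(v)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() + ggplot2::theme_void()
  add_contour <- function(p, m, colour) {
    mm <- take(m)
    dd <- df; dd$m <- as.vector(mm)
    p + ggplot2::geom_contour(data = dd, ggplot2::aes(z = .data$m),
                              breaks = 0.5, colour = colour, linewidth = 0.4)
  }
  if (!is.null(mask)) p <- add_contour(p, mask, "red")
  if (!is.null(pred)) p <- add_contour(p, pred, "cyan")
  p
}

#' @importFrom ggplot2 .data
NULL
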