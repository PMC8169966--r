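#' Global intensity-threshold baseline
#'
#' The simplest competitor a segmentation network must beat: a single
#' global intensity threshold chosen to maximize pooled Dice on training
#' volumes. Lesions share their intensity range with bright background
#' structures, so no global threshold can separate them well — the gap to
#' a trained network measures how much the network's spatial features buy.
#'
#' @param volumes List of normalized volumes (arrays or [seg_volume()]s).
#' @param masks List of aligned binary masks.
#' @param candidates Thresholds to scan.
#' @return Object of class `intensity_threshold` with fields `threshold`
#'   and `train_dice`.
#' @export
fit_intensity_threshold <- function(volumes, masks,
                                    candidates = seq(0.02, 0.98, by = 0.02)) {
  vs <- lapply(volumes, function(v) if (inherits(v, "seg_volume")) v$voxels else v)
  ms <- lapply(masks, function(m) if (inherits(m, "seg_volume")) m$voxels else m)
  x <- unlist(vs); y <- unlist(ms) > 0.5
  best_t <- candidates[1L]; best_d <- -1
  for (t in candidates) {
    p <- x >= t
    tp <- sum(p & y); fp <- sum(p & !y); fn <- sum(!p & y)
    d <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
    if (d > best_d) { best_d <- d; best_t <- t }
  }
  structure(list(threshold = best_t, train_dice = best_d),
            class = "intensity_threshold")
}

#' @export
predict.intensity_threshold <- function(object, volume, ...) {
  v <- if (inherits(volume, "seg_volume")) volume$voxels else volume
  array(as.numeric(v >= object$threshold), dim(v))
}

#' @export
print.intensity_threshold <- function(x, ...) {
  cat(sprintf("<intensity_threshold> t = %.2f (training Dice %.3f)\n",
              x$threshold, x$train_dice))
  invisible(x)
}
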