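#' Segment a volume with a trained OCunet
#'
#' Pads the input to a network-legal grid, runs one forward pass (or a
#' mean-blended sliding window with 50% overlap when `patch_size` is
#' given), crops back to the input grid and binarizes the foreground
#' probability at `threshold`. No morphological post-processing is
#' applied: the segmentation is the thresholded network output.
#'
#' @param object An `ocunet_fit`, an `ocunet_checkpoint` (see
#'   [load_checkpoint()]), or a checkpoint path.
#' @param volume A [seg_volume()] or array, values in `[0, 1]`.
#' @param patch_size Optional window dims (each divisible by
#'   `2^(levels+1)`); when `NULL` the whole padded volume is processed in
#'   one pass.
#' @param threshold Binarization threshold on the foreground probability.
#' @param use_best Prefer the best-by-validation parameters when present.
#' @return List of class `ocunet_prediction` with `prob` (foreground
#'   probability array on the input grid, values in `[0, 1]`) and `mask`
#'   (binary array).
#' @export
predict_ocunet <- function(object, volume, patch_size = NULL, threshold = 0.5,
                           use_best = TRUE) {
  if (is.character(object)) object <- load_checkpoint(object)
  if (inherits(object, "ocunet_fit")) {
    params <- if (use_best && !is.null(object$best_params)) object$best_params else object$params
    net <- object$config$network
  } else if (inherits(object, "ocunet_checkpoint")) {
    params <- object$params
    net <- object$config$network
  } else .stopf("object must be an ocunet_fit, checkpoint, or checkpoint path")

  vox <- if (inherits(volume, "seg_volume")) volume$voxels else volume
  if (length(dim(vox)) != net$dims)
    .stopf("volume is %d-D but the network is %d-D", length(dim(vox)), net$dims)
  padded <- pad_to_legal(vox, NULL, net$levels)
  pv <- if (inherits(padded$volume, "seg_volume")) padded$volume$voxels else padded$volume
  sp <- dim(pv)

  fg_of <- function(x) {
    dim(x) <- c(1L, dim(x))
    out <- .forward_net(params, net, list(x), training = FALSE)
    .take_channel(out$probs[[1L]], net$num_classes)
  }

  if (is.null(patch_size) || all(patch_size >= sp)) {
    prob <- fg_of(pv)
  } else {
    m <- .legal_multiple(net$levels)
    if (any(patch_size %% m != 0))
      .stopf("patch_size must be divisible by %d", m)
    if (any(patch_size > sp)) .stopf("patch_size exceeds the padded grid")
    starts <- lapply(seq_along(sp), function(a) {
      if (patch_size[a] >= sp[a]) return(1L)
      s <- seq.int(1L, sp[a] - patch_size[a] + 1L, by = max(1L, patch_size[a] %/% 2L))
      unique(c(s, sp[a] - patch_size[a] + 1L))
    })
    prob <- array(0, sp); wt <- array(0, sp)
    grid <- as.matrix(expand.grid(starts))
    for (r in seq_len(nrow(grid))) {
      org <- grid[r, ]
      idx <- lapply(seq_along(sp), function(a) org[a] + seq_len(patch_size[a]) - 1L)
      win <- do.call(`[`, c(list(pv), idx, list(drop = FALSE)))
      p_win <- fg_of(win)
      prob <- do.call(`[<-`, c(list(prob), idx,
                               list(value = do.call(`[`, c(list(prob), idx, list(drop = FALSE))) + p_win)))
      wt <- do.call(`[<-`, c(list(wt), idx,
                             list(value = do.call(`[`, c(list(wt), idx, list(drop = FALSE))) + 1)))
    }
    prob <- prob / wt
  }
  prob <- crop_to_original(prob, padded$crop)
  structure(list(prob = prob, mask = array(as.numeric(prob >= threshold), dim(prob)),
                 threshold = threshold),
            class = "ocunet_prediction")
}

#' @export
predict.ocunet_fit <- function(object, volume, ...) {
  predict_ocunet(object, volume, ...)
}

#' Segment every volume in a directory
#'
#' Reads each `caseNNNN_img.nii(.gz)`, predicts, and writes
#' `caseNNNN_pred.nii.gz` (binary mask) and `caseNNNN_prob.nii.gz`
#' (foreground probability) to `out_dir`.
#'
#' @inheritParams predict_ocunet
#' @param in_dir Directory of input images.
#' @param out_dir Output directory (created if missing).
#' @return Tibble of case ids and output paths, invisibly.
#' @export
predict_dir <- function(object, in_dir, out_dir, patch_size = NULL, threshold = 0.5) {
  imgs <- sort(list.files(in_dir, pattern = "_img\\.nii(\\.gz)?$", full.names = TRUE))
  if (length(imgs) == 0L) .stopf("no caseNNNN_img.nii(.gz) files found in %s", in_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(imgs, function(f) {
    vol <- read_volume(f)
    pr <- predict_ocunet(object, vol, patch_size = patch_size, threshold = threshold)
    id <- sub("_img\\.nii(\\.gz)?$", "", basename(f))
    mask_path <- file.path(out_dir, paste0(id, "_pred.nii.gz"))
    prob_path <- file.path(out_dir, paste0(id, "_prob.nii.gz"))
    write_mask(label_mask(pr$mask, vol$spacing, vol$header), mask_path)
    write_volume(seg_volume(pr$prob, vol$spacing, vol$header), prob_path)
    tibble::tibble(case = id, mask = mask_path, prob = prob_path)
  })
  invisible(do.call(rbind, rows))
}
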