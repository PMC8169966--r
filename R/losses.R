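#' Soft Dice loss
#'
#' Differentiable relaxation of the Dice overlap to probability maps:
#' `1 - (2 * sum(p * t) + s) / (sum(p) + sum(t) + s)` with smoothing
#' constant `s`. Chosen as the training objective because tumor voxels are
#' vastly outnumbered by background voxels, a regime in which per-voxel
#' cross-entropy biases predictions toward background.
#'
#' @param prob Foreground probability array, values in `[0, 1]`.
#' @param truth Binary array on the same grid.
#' @param smooth Small positive smoothing constant.
#' @return Scalar loss in `[0, 1]`.
#' @export
soft_dice_loss <- function(prob, truth, smooth = 1e-5) {
  if (!identical(dim(prob), dim(truth)) &&
      !identical(as.integer(dim(prob)), as.integer(dim(truth))))
    .stopf("prob and truth grids differ: (%s) vs (%s)",
           paste(dim(prob), collapse = "x"), paste(dim(truth), collapse = "x"))
  if (min(prob) < -1e-12 || max(prob) > 1 + 1e-12)
    .stopf("prob values must lie in [0, 1]")
  1 - (2 * sum(prob * truth) + smooth) / (sum(prob) + sum(truth) + smooth)
}

# gradient of soft_dice_loss w.r.t. prob
.soft_dice_grad <- function(prob, truth, smooth = 1e-5) {
  num <- 2 * sum(prob * truth) + smooth
  den <- sum(prob) + sum(truth) + smooth
  (num / den^2) - (2 * truth) / den
}

#' Deep-supervision loss weights
#'
#' Weights of the composite objective: the final output plus up to two
#' auxiliary branches, ordered shallowest (nearest the output) first.
#'
#' @param main Weight of the final-output loss (> 0).
#' @param aux Numeric vector of auxiliary weights (>= 0), shallowest first.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(main = 1, aux = c(0.5, 0.25)) {
  if (!is.numeric(main) || length(main) != 1L || main <= 0) .stopf("main weight must be > 0")
  if (length(aux) && any(aux < 0)) .stopf("aux weights must be >= 0")
  structure(list(main = main, aux = as.numeric(aux)), class = "loss_weights")
}

#' Deeply supervised composite Dice loss
#'
#' `weights$main * L(main) + sum_j weights$aux[j] * L(aux_j)` where each
#' `L` is the soft Dice loss of the branch's foreground probability against
#' the ground truth. Auxiliary gradients injected at hidden layers
#' counteract vanishing gradients in deep encoder-decoder stacks.
#'
#' @param outputs An `ocunet_outputs` object (or a list with `main_prob`
#'   and `aux_probs`), all maps at input resolution.
#' @param truth Binary ground-truth array on the prediction grid.
#' @param weights A [loss_weights()]; `length(weights$aux)` must equal
#'   `length(outputs$aux_probs)`.
#' @param smooth Smoothing constant passed to [soft_dice_loss()].
#' @return Scalar composite loss.
#' @export
deep_supervised_loss <- function(outputs, truth, weights = loss_weights(aux = numeric(0)),
                                 smooth = 1e-5) {
  n_aux <- length(outputs$aux_probs)
  if (length(weights$aux) != n_aux)
    .stopf("got %d aux weights for %d aux branches", length(weights$aux), n_aux)
  fg <- function(p) .take_channel(p, dim(p)[1L])
  total <- weights$main * soft_dice_loss(fg(outputs$main_prob), truth, smooth)
  for (j in seq_len(n_aux))
    total <- total + weights$aux[j] * soft_dice_loss(fg(outputs$aux_probs[[j]]), truth, smooth)
  total
}
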