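#' Voxel-wise confusion counts
#'
#' Exact TP/FP/TN/FN counts between a predicted and a reference binary
#' mask on the same grid.
#'
#' @param pred,truth Binary arrays (values 0/1 or logical) on one grid.
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn`; the four counts sum to the grid size.
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(as.integer(dim(pred)), as.integer(dim(truth))))
    .stopf("pred and truth grids differ: (%s) vs (%s)",
           paste(dim(pred), collapse = "x"), paste(dim(truth), collapse = "x"))
  p <- as.logical(pred); t <- as.logical(truth)
  if (anyNA(p) || anyNA(t)) .stopf("masks must not contain NA")
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%d fp=%d tn=%d fn=%d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

# zero-denominator convention: 1 when the denominator is empty and the
# masks agree trivially, else 0 — never NaN
.safe_ratio <- function(num, den, agree) {
  if (den == 0) return(if (agree) 1 else 0)
  num / den
}

#' Segmentation evaluation metrics
#'
#' Computes precision `TP/(TP+FP)`, recall (sensitivity) `TP/(TP+FN)`,
#' accuracy `(TP+TN)/total`, specificity `TN/(FP+TN)` and the Dice overlap
#' `2|A n B| / (|A| + |B|)` between a predicted mask A and reference mask
#' B. Dice is computed both directly on the masks and through the
#' equivalent confusion identity `2TP/(2TP+FP+FN)`; the two routes must
#' agree exactly. Metrics with an empty denominator follow the standard
#' benchmark convention: 1 when the masks agree trivially (e.g. Dice of
#' two empty masks), 0 otherwise.
#'
#' @param pred,truth Binary arrays on one grid.
#' @param counts Optional precomputed [confusion_counts()]; when omitted
#'   they are computed from the masks.
#' @return A one-row tibble with columns `precision`, `recall`,
#'   `accuracy`, `specificity`, `dice`, `tp`, `fp`, `tn`, `fn`.
#' @examples
#' a <- array(0, c(10, 10)); a[3:5, 3:5] <- 1
#' compute_metrics(a, a)$dice  # identical masks overlap completely: 1
#' @export
compute_metrics <- function(pred, truth, counts = NULL) {
  if (is.null(counts)) counts <- confusion_counts(pred, truth)
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn

  # direct mask route for Dice: 2|A n B| / (|A| + |B|)
  inter <- sum(as.logical(pred) & as.logical(truth))
  size_a <- sum(as.logical(pred)); size_b <- sum(as.logical(truth))
  dice_masks <- .safe_ratio(2 * inter, size_a + size_b, size_a + size_b == 0)
  dice_counts <- .safe_ratio(2 * tp, 2 * tp + fp + fn, fp + fn == 0)
  if (!isTRUE(all.equal(dice_masks, dice_counts, tolerance = 0)))
    .stopf("internal inconsistency: Dice routes disagree (%g vs %g)", dice_masks, dice_counts)

  tibble::tibble(
    precision = .safe_ratio(tp, tp + fp, fn == 0),
    recall = .safe_ratio(tp, tp + fn, fp == 0),
    accuracy = .safe_ratio(tp + tn, total, TRUE),
    specificity = .safe_ratio(tn, fp + tn, fn == 0),
    dice = dice_masks,
    tp = tp, fp = fp, tn = tn, fn = fn)
}
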