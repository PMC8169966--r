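#' Evaluate predicted masks against reference masks
#'
#' Computes the per-case metric table plus two cohort summaries: the mean
#' of the per-case metrics (`"mean"`) and the metrics of the voxel-pooled
#' confusion counts (`"pooled"`). Both conventions are reported because
#' cohort-level published tables rarely state which one they use.
#'
#' Inputs are either named lists of binary arrays or directories;
#' directories are matched by case id (file name up to the first `_pred`
#' / `_seg` suffix). Unmatched cases are excluded with a warning and
#' listed in the `unmatched` attribute.
#'
#' @param pred Directory of `*_pred.nii.gz` files, or named list of masks.
#' @param truth Directory of `*_seg.nii.gz` files, or named list of masks.
#' @param label Optional label of interest for reading truth masks.
#' @return Tibble with a `case` column followed by the metric columns of
#'   [compute_metrics()].
#' @export
evaluate_segmentations <- function(pred, truth, label = NULL) {
  read_dir <- function(dir, pattern, strip) {
    fs <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
    masks <- lapply(fs, function(f) read_mask(f, label = label)$voxels)
    names(masks) <- sub(strip, "", basename(fs))
    masks
  }
  if (is.character(pred))
    pred <- read_dir(pred, "_pred\\.nii(\\.gz)?$", "_pred\\.nii(\\.gz)?$")
  if (is.character(truth))
    truth <- read_dir(truth, "_seg\\.nii(\\.gz)?$", "_seg\\.nii(\\.gz)?$")
  if (is.null(names(pred)) || is.null(names(truth)))
    .stopf("pred and truth must be named by case")
  common <- intersect(names(pred), names(truth))
  unmatched <- setdiff(union(names(pred), names(truth)), common)
  if (length(unmatched))
    warning("unmatched cases excluded: ", paste(unmatched, collapse = ", "), call. = FALSE)
  if (length(common) == 0L) .stopf("no matched cases to evaluate")

  per_case <- do.call(rbind, lapply(common, function(id) {
    m <- compute_metrics(pred[[id]], truth[[id]])
    cbind(tibble::tibble(case = id), m)
  }))
  metric_cols <- c("precision", "recall", "accuracy", "specificity", "dice")
  mean_row <- cbind(tibble::tibble(case = "mean"),
                    as_tibble(as.list(colMeans(per_case[metric_cols]))),
                    tibble::tibble(tp = NA_integer_, fp = NA_integer_,
                                   tn = NA_integer_, fn = NA_integer_))
  pooled_counts <- structure(list(tp = sum(per_case$tp), fp = sum(per_case$fp),
                                  tn = sum(per_case$tn), fn = sum(per_case$fn)),
                             class = "confusion_counts")
  # pooled Dice uses the count identity; mask route needs the full cohort, so
  # rebuild it from the identity-equivalent counts
  pooled_row <- cbind(
    tibble::tibble(case = "pooled"),
    tibble::tibble(
      precision = .safe_ratio(pooled_counts$tp, pooled_counts$tp + pooled_counts$fp,
                              pooled_counts$fn == 0),
      recall = .safe_ratio(pooled_counts$tp, pooled_counts$tp + pooled_counts$fn,
                           pooled_counts$fp == 0),
      accuracy = .safe_ratio(pooled_counts$tp + pooled_counts$tn,
                             pooled_counts$tp + pooled_counts$fp +
                               pooled_counts$tn + pooled_counts$fn, TRUE),
      specificity = .safe_ratio(pooled_counts$tn, pooled_counts$fp + pooled_counts$tn,
                                pooled_counts$fn == 0),
      dice = .safe_ratio(2 * pooled_counts$tp,
                         2 * pooled_counts$tp + pooled_counts$fp + pooled_counts$fn,
                         pooled_counts$fp + pooled_counts$fn == 0),
      tp = pooled_counts$tp, fp = pooled_counts$fp,
      tn = pooled_counts$tn, fn = pooled_counts$fn))
  out <- rbind(per_case, mean_row, pooled_row)
  attr(out, "unmatched") <- unmatched
  out
}

#' Write a metrics table as text report and structured file
#'
#' Emits a line-oriented `key<TAB>value` table per case plus the cohort
#' rows, and a machine-readable JSON file with the same content.
#'
#' @param metrics Tibble from [evaluate_segmentations()].
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return Named vector of the two paths, invisibly.
#' @export
write_metrics_report <- function(metrics, prefix) {
  tsv <- paste0(prefix, ".tsv"); json <- paste0(prefix, ".json")
  dir.create(dirname(tsv), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(metrics, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(metrics, json, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(c(tsv = tsv, json = json))
}
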