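#' Construct a segmentation volume
#'
#' Lightweight container for a dense scalar grid (2-D slice or 3-D volume)
#' with physical voxel spacing and an optional NIfTI header carried
#' through I/O.
#'
#' @param voxels Numeric array (spatial dims only).
#' @param spacing Positive voxel size per axis, in mm.
#' @param header Optional NIfTI header (as returned by [RNifti::niftiHeader()])
#'   preserved verbatim on write.
#' @return An object of class `seg_volume`.
#' @export
seg_volume <- function(voxels, spacing = rep(1, length(dim(voxels))), header = NULL) {
  if (is.null(dim(voxels))) .stopf("voxels must be an array")
  if (length(spacing) != length(dim(voxels)) || any(spacing <= 0))
    .stopf("spacing must be positive, one value per axis")
  structure(list(voxels = voxels, spacing = as.numeric(spacing), header = header),
            class = "seg_volume")
}

#' @export
print.seg_volume <- function(x, ...) {
  cat(sprintf("<seg_volume> %s voxels, spacing (%s) mm, range [%g, %g]\n",
              paste(dim(x$voxels), collapse = " x "),
              paste(signif(x$spacing, 4), collapse = ", "),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Construct a binary label mask
#'
#' @param voxels Array of 0/1 (or logical) values aligned to a volume grid.
#' @param spacing Positive voxel size per axis, in mm.
#' @param header Optional NIfTI header preserved on write.
#' @return An object of class `label_mask` (also a `seg_volume`).
#' @export
label_mask <- function(voxels, spacing = rep(1, length(dim(voxels))), header = NULL) {
  v <- seg_volume(voxels, spacing, header)
  if (!all(v$voxels %in% c(0, 1))) .stopf("mask values must be 0/1")
  storage.mode(v$voxels) <- "double"
  class(v) <- c("label_mask", "seg_volume")
  v
}

.nifti_spacing <- function(img) {
  pd <- RNifti::pixdim(img)
  pd[seq_len(length(dim(img)))]
}

#' Read a NIfTI volume
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return A [seg_volume()] with spacing and header taken from the file.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  img <- RNifti::readNifti(path)
  seg_volume(array(as.numeric(img), dim(img)), .nifti_spacing(img),
             header = RNifti::niftiHeader(img))
}

#' Write a volume to NIfTI
#'
#' Round-trips exactly: values, grid, spacing and (when present) the
#' original header are preserved.
#'
#' @param vol A [seg_volume()] or plain array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!inherits(vol, "seg_volume")) vol <- seg_volume(vol)
  img <- if (!is.null(vol$header)) {
    RNifti::asNifti(vol$voxels, reference = vol$header)
  } else {
    pd <- rep(0, 8)
    pd[1L] <- -1
    pd[1L + seq_along(vol$spacing)] <- vol$spacing
    RNifti::asNifti(vol$voxels, reference = list(pixdim = pd))
  }
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a NIfTI label mask
#'
#' By default any value above 0.5 maps to foreground. Supplying `label`
#' selects one integer label as foreground instead (e.g. `label = 2` for
#' the LiTS convention 0 = background, 1 = liver, 2 = tumor).
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param label Optional integer label of interest.
#' @return A [label_mask()].
#' @export
read_mask <- function(path, label = NULL) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  img <- RNifti::readNifti(path)
  v <- array(as.numeric(img), dim(img))
  bin <- if (is.null(label)) (v > 0.5) else (v == label)
  label_mask(array(as.numeric(bin), dim(v)), .nifti_spacing(img),
             header = RNifti::niftiHeader(img))
}

#' @rdname read_mask
#' @param mask A [label_mask()] or binary array.
#' @export
write_mask <- function(mask, path) {
  write_volume(mask, path)
}

#' Normalize intensities to the unit interval
#'
#' Optionally clips to an intensity window (e.g. a liver CT window in
#' Hounsfield units) and then maps affinely so the window (or observed)
#' minimum goes to 0 and maximum to 1. Monotone, idempotent on its own
#' output when no window is given. A constant input maps to 0.5 everywhere
#' with a warning.
#'
#' @param vol A [seg_volume()] or array.
#' @param window Optional `c(lo, hi)` clipping window applied before
#'   scaling (default `NULL`: min-max of the data).
#' @return Same type as `vol`, values in `[0, 1]`.
#' @export
normalize_intensity <- function(vol, window = NULL) {
  is_sv <- inherits(vol, "seg_volume")
  v <- if (is_sv) vol$voxels else vol
  if (!is.null(window)) {
    if (length(window) != 2L || window[2L] <= window[1L]) .stopf("window must be c(lo, hi), lo < hi")
    v <- pmin(pmax(v, window[1L]), window[2L])
    lo <- window[1L]; hi <- window[2L]
  } else {
    lo <- min(v); hi <- max(v)
  }
  if (hi == lo) {
    warning("constant input; returning 0.5 everywhere", call. = FALSE)
    out <- array(0.5, dim(v))
  } else {
    out <- (v - lo) / (hi - lo)
  }
  if (is_sv) { vol$voxels <- out; vol } else out
}

#' Pad a volume/mask pair to a network-legal grid
#'
#' Pads every axis up to the nearest multiple of `2^(levels + 1)` (the
#' octave shape law: one extra halving below the deepest level). The
#' volume is padded with its edge values, the mask with zeros. The
#' returned crop record inverts the padding exactly.
#'
#' @param vol A [seg_volume()] or array.
#' @param mask Optional aligned mask.
#' @param levels Number of network down-sampling stages.
#' @return List with `volume`, `mask` (or `NULL`) and `crop` (per-axis
#'   index ranges of the original grid inside the padded one).
#' @seealso [crop_to_original()]
#' @export
pad_to_legal <- function(vol, mask = NULL, levels) {
  is_sv <- inherits(vol, "seg_volume")
  v <- if (is_sv) vol$voxels else vol
  sp <- dim(v)
  m <- .legal_multiple(levels)
  total <- (m - sp %% m) %% m
  left <- total %/% 2L; right <- total - left
  idx <- lapply(seq_along(sp), function(a)
    c(rep(1L, left[a]), seq_len(sp[a]), rep(sp[a], right[a])))
  pv <- do.call(`[`, c(list(v), idx, list(drop = FALSE)))
  crop <- lapply(seq_along(sp), function(a) as.integer(left[a] + seq_len(sp[a])))
  pm <- NULL
  if (!is.null(mask)) {
    mv <- if (inherits(mask, "seg_volume")) mask$voxels else mask
    if (!identical(as.integer(dim(mv)), as.integer(sp)))
      .stopf("mask grid (%s) does not match volume grid (%s)",
             paste(dim(mv), collapse = "x"), paste(sp, collapse = "x"))
    pm <- array(0, sp + total)
    pm <- do.call(`[<-`, c(list(pm), crop, list(value = mv)))
  }
  out_vol <- if (is_sv) seg_volume(pv, vol$spacing, vol$header) else pv
  out_mask <- if (!is.null(pm)) {
    if (inherits(mask, "seg_volume")) label_mask(pm, mask$spacing, mask$header) else pm
  }
  list(volume = out_vol, mask = out_mask, crop = crop)
}

#' Undo legal-shape padding
#'
#' @param x Array (or `seg_volume`) on the padded grid.
#' @param crop Crop record from [pad_to_legal()].
#' @return The array restricted to the original grid.
#' @export
crop_to_original <- function(x, crop) {
  is_sv <- inherits(x, "seg_volume")
  v <- if (is_sv) x$voxels else x
  out <- do.call(`[`, c(list(v), crop, list(drop = FALSE)))
  if (is_sv) { x$voxels <- out; x } else out
}

#' Sample aligned training patches
#'
#' Draws `n_patches` aligned (volume, mask) patches, a fraction of which
#' is guaranteed to contain at least one foreground voxel (foreground-
#' biased sampling against the heavy class imbalance of tumor masks).
#' Deterministic given `seed`.
#'
#' @param vol A [seg_volume()] or array.
#' @param mask Aligned binary mask.
#' @param patch_size Integer patch dims (one per axis).
#' @param n_patches Number of patches to draw.
#' @param fg_fraction Fraction of patches forced to intersect foreground.
#' @param seed Optional RNG seed.
#' @return List of `list(volume =, mask =, origin =)` patch records.
#' @export
extract_patches <- function(vol, mask, patch_size, n_patches = 16,
                            fg_fraction = 0.5, seed = NULL) {
  v <- if (inherits(vol, "seg_volume")) vol$voxels else vol
  mv <- if (inherits(mask, "seg_volume")) mask$voxels else mask
  sp <- dim(v)
  if (length(patch_size) != length(sp)) .stopf("patch_size must have %d dims", length(sp))
  if (any(patch_size > sp)) .stopf("patch (%s) larger than grid (%s)",
                                   paste(patch_size, collapse = "x"), paste(sp, collapse = "x"))
  if (fg_fraction < 0 || fg_fraction > 1) .stopf("fg_fraction must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  fg_idx <- which(mv > 0.5, arr.ind = TRUE)
  n_fg <- round(fg_fraction * n_patches)
  if (n_fg > 0 && nrow(fg_idx) == 0L) .stopf("foreground-biased sampling requested but mask is empty")
  out <- vector("list", n_patches)
  for (i in seq_len(n_patches)) {
    if (i <= n_fg) {
      ctr <- fg_idx[sample.int(nrow(fg_idx), 1L), ]
      org <- pmin(pmax(ctr - sapply(patch_size, function(p) sample.int(p, 1L)) + 1L, 1L),
                  sp - patch_size + 1L)
    } else {
      org <- sapply(seq_along(sp), function(a) sample.int(sp[a] - patch_size[a] + 1L, 1L))
    }
    idx <- lapply(seq_along(sp), function(a) org[a] + seq_len(patch_size[a]) - 1L)
    out[[i]] <- list(volume = do.call(`[`, c(list(v), idx, list(drop = FALSE))),
                     mask = do.call(`[`, c(list(mv), idx, list(drop = FALSE))),
                     origin = as.integer(org))
  }
  out
}
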