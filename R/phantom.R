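#' Specify a synthetic CT phantom
#'
#' The phantom generator realizes the frequency decomposition that
#' motivates multifrequency feature learning: a smooth low-spatial-
#' frequency background (a superposition of broad Gaussian bumps emulating
#' slowly varying anatomy) plus sharp-edged ellipsoidal lesions whose hard
#' boundaries are maximally high-frequency, plus additive noise. The
#' ground-truth mask is the exact union of the lesion interiors.
#'
#' @param shape Grid dims (2 or 3 axes).
#' @param n_lesions Inclusive count range `c(min, max)`.
#' @param lesion_radius Range of ellipsoid semi-axes, in voxels (>= 1).
#' @param lesion_contrast Range of the additive intensity offset inside a
#'   lesion; its lower end must exceed `noise_sd` so lesions are
#'   detectable in principle.
#' @param background_smoothness Range of Gaussian bump scales (sd, voxels).
#' @param n_bumps Inclusive range of background bump counts.
#' @param bump_amplitude Range of background bump amplitudes.
#' @param noise_sd Additive zero-mean Gaussian noise scale.
#' @param seed Optional RNG seed making generation fully deterministic.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64), n_lesions = c(1, 3),
                         lesion_radius = c(3, 6), lesion_contrast = c(0.3, 0.5),
                         background_smoothness = c(8, 16), n_bumps = c(3, 6),
                         bump_amplitude = c(0.1, 0.4), noise_sd = 0.05,
                         seed = NULL) {
  if (!length(shape) %in% c(2L, 3L)) .stopf("shape must have 2 or 3 axes")
  rng2 <- function(x) if (length(x) == 1L) c(x, x) else sort(x[1:2])
  n_lesions <- rng2(n_lesions); lesion_radius <- rng2(lesion_radius)
  lesion_contrast <- rng2(lesion_contrast)
  background_smoothness <- rng2(background_smoothness)
  n_bumps <- rng2(n_bumps); bump_amplitude <- rng2(bump_amplitude)
  if (lesion_radius[1L] < 1) .stopf("lesion radii must be >= 1 voxel")
  if (lesion_contrast[1L] <= noise_sd)
    .stopf("lesion contrast (%g) must exceed noise_sd (%g)", lesion_contrast[1L], noise_sd)
  structure(list(shape = as.integer(shape), n_lesions = n_lesions,
                 lesion_radius = lesion_radius, lesion_contrast = lesion_contrast,
                 background_smoothness = background_smoothness, n_bumps = n_bumps,
                 bump_amplitude = bump_amplitude, noise_sd = noise_sd, seed = seed),
            class = "phantom_spec")
}

# voxel-centre coordinate grids, one array per axis
.coord_grids <- function(shape) {
  d <- length(shape)
  lapply(seq_len(d), function(a) {
    perm <- rep(1, d); perm[a] <- shape[a]
    aperm(array(rep(seq_len(shape[a]), times = prod(shape[-a])),
                c(shape[a], shape[-a])),
          order(c(a, seq_len(d)[-a])))
  })
}

#' Generate a synthetic phantom volume and mask
#'
#' Draws the background, lesions and noise described by the spec, then
#' normalizes the volume to `[0, 1]`. Deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` (a [seg_volume()], values in `[0, 1]`),
#'   `mask` (a [label_mask()]) and `lesions` (a list of sampled centre/
#'   semi-axis records, usable to re-rasterize the mask independently).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  shape <- spec$shape; d <- length(shape)
  grids <- .coord_grids(shape)

  vol <- array(0.2, shape)
  nb <- sample(spec$n_bumps[1L]:spec$n_bumps[2L], 1L)
  for (b in seq_len(nb)) {
    ctr <- runif(d, 1, shape)
    sig <- runif(1, spec$background_smoothness[1L], spec$background_smoothness[2L])
    amp <- runif(1, spec$bump_amplitude[1L], spec$bump_amplitude[2L])
    d2 <- 0
    for (a in seq_len(d)) d2 <- d2 + (grids[[a]] - ctr[a])^2
    vol <- vol + amp * exp(-d2 / (2 * sig^2))
  }

  n_les <- sample(spec$n_lesions[1L]:spec$n_lesions[2L], 1L)
  mask <- array(0, shape)
  lesions <- vector("list", n_les)
  for (k in seq_len(n_les)) {
    semi <- runif(d, spec$lesion_radius[1L], spec$lesion_radius[2L])
    if (any(2 * semi + 2 > shape))
      .stopf("lesion semi-axes (%s) cannot fit the grid (%s)",
             paste(signif(semi, 3), collapse = ", "), paste(shape, collapse = "x"))
    ctr <- sapply(seq_len(d), function(a) runif(1, semi[a] + 1, shape[a] - semi[a]))
    contrast <- runif(1, spec$lesion_contrast[1L], spec$lesion_contrast[2L])
    r2 <- 0
    for (a in seq_len(d)) r2 <- r2 + ((grids[[a]] - ctr[a]) / semi[a])^2
    inside <- r2 <= 1
    vol <- vol + contrast * inside
    mask[inside] <- 1
    lesions[[k]] <- list(centre = ctr, semi_axes = semi, contrast = contrast)
  }

  if (spec$noise_sd > 0) vol <- vol + rnorm(length(vol), sd = spec$noise_sd)
  vol <- (vol - min(vol)) / (max(vol) - min(vol))
  list(volume = seg_volume(vol), mask = label_mask(mask), lesions = lesions)
}

#' Write a phantom dataset to disk
#'
#' Emits paired `caseNNNN_img.nii.gz` / `caseNNNN_seg.nii.gz` files plus a
#' YAML manifest recording the spec and the per-case seeds, so any case is
#' exactly regenerable.
#'
#' @param n_cases Number of cases.
#' @param spec A [phantom_spec()]; its `seed` seeds the per-case stream.
#' @param dir Output directory (created if missing).
#' @param seed Base seed; case `i` uses `seed + i`.
#' @return Tibble manifest (case id, paths, seed), invisibly.
#' @export
generate_phantom_dataset <- function(n_cases, spec, dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    case_seed <- as.integer(seed) + i
    sp <- spec; sp$seed <- case_seed
    ph <- generate_phantom(sp)
    id <- sprintf("case%04d", i)
    img_path <- file.path(dir, paste0(id, "_img.nii.gz"))
    seg_path <- file.path(dir, paste0(id, "_seg.nii.gz"))
    write_volume(ph$volume, img_path)
    write_mask(ph$mask, seg_path)
    rows[[i]] <- tibble::tibble(case = id, image = img_path, mask = seg_path,
                                seed = case_seed)
  }
  manifest <- do.call(rbind, rows)
  spec_out <- unclass(spec); spec_out$seed <- NULL
  yaml::write_yaml(list(spec = spec_out, base_seed = as.integer(seed),
                        cases = lapply(seq_len(n_cases), function(i)
                          list(case = manifest$case[i], seed = manifest$seed[i]))),
                   file.path(dir, "manifest.yaml"))
  invisible(manifest)
}
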