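test_that("NIfTI volumes round-trip values, grid and spacing exactly", {
  set.seed(41)
  vol <- seg_volume(array(runif(16^3), c(16, 16, 16)), spacing = c(0.7, 0.7, 2.5))
  path <- file.path(tempdir(), "rt.nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(back$voxels, vol$voxels)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)  # pixdim is float32
  expect_error(read_volume(file.path(tempdir(), "nope.nii.gz")), "nope")
})

test_that("mask reading binarizes and honors a label of interest", {
  lab <- array(0, c(8, 8)); lab[2:3, 2:3] <- 2; lab[6:7, 6:7] <- 1  # LiTS-style
  path <- file.path(tempdir(), "mask.nii.gz")
  write_volume(seg_volume(lab), path)
  tumor <- read_mask(path, label = 2)
  expect_identical(sort(unique(as.vector(tumor$voxels))), c(0, 1))
  expect_equal(sum(tumor$voxels), 4)
  expect_equal(tumor$voxels[2, 2], 1)
  any_fg <- read_mask(path)  # default: > 0.5
  expect_equal(sum(any_fg$voxels), 8)
})

test_that("intensity normalization clips, rescales, and is idempotent", {
  x <- array(c(-1000, 0, 1000, 250, -200, 25), c(2, 3))
  out <- normalize_intensity(x, window = c(-200, 250))
  expect_equal(out[1, 1], 0)
  expect_equal(out[2, 2], 1)       # 1000 clipped to 250
  expect_equal(out[2, 1], 200 / 450)
  expect_true(all(out >= 0 & out <= 1))
  # monotone on unclipped values
  expect_true(out[1, 3] < out[2, 3])
  y <- array(runif(50), c(5, 10))
  y01 <- normalize_intensity(y)
  expect_equal(normalize_intensity(y01), y01, tolerance = 1e-12)
  expect_warning(z <- normalize_intensity(array(3, c(4, 4))), "constant")
  expect_true(all(z == 0.5))
})

test_that("legal-shape padding is exact and exactly invertible", {
  set.seed(42)
  v <- array(runif(50 * 50), c(50, 50))
  m <- array(rbinom(50 * 50, 1, 0.1), c(50, 50))
  p <- pad_to_legal(v, m, levels = 3)
  expect_identical(dim(p$volume), c(64L, 64L))
  expect_identical(dim(p$mask), c(64L, 64L))
  expect_equal(crop_to_original(p$volume, p$crop), v)
  expect_equal(crop_to_original(p$mask, p$crop), m)
  # volume uses edge values, mask zero-fills
  expect_equal(p$volume[1, p$crop[[2]]], v[1, ])
  expect_true(all(p$mask[1:(p$crop[[1]][1] - 1), ] == 0))
  ok <- pad_to_legal(array(runif(64 * 64), c(64, 64)), NULL, levels = 3)
  expect_identical(dim(ok$volume), c(64L, 64L))
  expect_identical(ok$crop, list(1:64, 1:64))
})

test_that("patch extraction is deterministic, aligned, and foreground-biased", {
  set.seed(43)
  v <- array(runif(48 * 48), c(48, 48))
  m <- array(0, c(48, 48)); m[20:24, 30:33] <- 1
  ps <- extract_patches(v, m, c(16, 16), n_patches = 10, fg_fraction = 1, seed = 5)
  for (p in ps) {
    expect_gt(sum(p$mask), 0)  # every patch intersects the lesion
    idx <- list(p$origin[1] + 0:15, p$origin[2] + 0:15)
    expect_equal(p$volume, v[idx[[1]], idx[[2]], drop = FALSE])
    expect_equal(p$mask, m[idx[[1]], idx[[2]], drop = FALSE])
  }
  ps2 <- extract_patches(v, m, c(16, 16), n_patches = 10, fg_fraction = 1, seed = 5)
  expect_identical(ps, ps2)
  expect_error(extract_patches(v, m, c(64, 64)), "larger")
})

test_that("phantom generation is deterministic with contrasted, rasterizable lesions", {
  spec <- phantom_spec(shape = c(48, 48), seed = 99, lesion_radius = c(3, 5))
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$mask$voxels, b$mask$voxels)
  expect_true(all(a$volume$voxels >= 0 & a$volume$voxels <= 1))
  fg <- mean(a$mask$voxels)
  expect_gt(fg, 0)
  expect_lt(fg, 0.15)  # imbalance regime: foreground is rare
  # independent rasterization oracle from the sampled ellipsoid records
  oracle <- array(0, c(48, 48))
  for (i in 1:48) for (j in 1:48) {
    for (les in a$lesions) {
      r2 <- ((i - les$centre[1]) / les$semi_axes[1])^2 +
        ((j - les$centre[2]) / les$semi_axes[2])^2
      if (r2 <= 1) oracle[i, j] <- 1
    }
  }
  expect_identical(a$mask$voxels, oracle)
  # noise-free phantom: lesions are strictly brighter than background
  clean <- generate_phantom(phantom_spec(shape = c(48, 48), noise_sd = 0,
                                         lesion_contrast = c(0.5, 0.5), seed = 7))
  inside <- clean$volume$voxels[clean$mask$voxels == 1]
  outside <- clean$volume$voxels[clean$mask$voxels == 0]
  expect_gt(mean(inside), mean(outside))
  expect_error(generate_phantom(phantom_spec(shape = c(8, 8),
                                             lesion_radius = c(6, 6), seed = 1)),
               "fit")
  expect_error(phantom_spec(lesion_contrast = c(0.01, 0.1), noise_sd = 0.05),
               "noise")
})

test_that("phantom datasets land on disk with an exact manifest", {
  dir <- file.path(tempdir(), "phantoms")
  unlink(dir, recursive = TRUE)
  man <- generate_phantom_dataset(3, phantom_spec(shape = c(32, 32)), dir, seed = 11)
  expect_identical(nrow(man), 3L)
  expect_true(all(file.exists(man$image), file.exists(man$mask)))
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  # a case regenerated from its manifest seed matches the file bit for bit
  y <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  sp <- do.call(phantom_spec, c(y$spec, list(seed = y$cases[[2]]$seed)))
  regen <- generate_phantom(sp)
  expect_equal(read_volume(man$image[2])$voxels, regen$volume$voxels)
  expect_equal(read_mask(man$mask[2])$voxels, regen$mask$voxels)
})
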