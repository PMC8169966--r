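test_that("shape planning mirrors encoder and decoder and enforces divisibility", {
  cfg <- ocunet_config(dims = 2, levels = 2, base_channels = 8, alpha = 0.5,
                       aux_branches = 1)
  tab <- plan_shapes(cfg, c(64, 64))
  row <- function(stage, level, branch) tab[tab$stage == stage & tab$level == level &
                                              tab$branch == branch, ]
  expect_identical(row("encoder", 1, "high")$channels, 4L)
  expect_identical(row("encoder", 1, "high")$spatial[[1]], c(64L, 64L))
  expect_identical(row("encoder", 1, "low")$spatial[[1]], c(32L, 32L))
  expect_identical(row("encoder", 2, "high")$channels, 8L)
  expect_identical(row("encoder", 2, "high")$spatial[[1]], c(32L, 32L))
  expect_identical(row("encoder", 2, "low")$spatial[[1]], c(16L, 16L))
  # decoder mirrors the encoder level by level
  for (l in 1:2) for (br in c("high", "low"))
    expect_identical(row("decoder", l, br)$spatial, row("encoder", l, br)$spatial)
  expect_identical(row("decoder", 1, "high")$spatial[[1]], c(64L, 64L))
  cfg3 <- ocunet_config(levels = 3, base_channels = 8)
  expect_error(plan_shapes(cfg3, c(50, 50)), "divisible by 16")
})

test_that("encoder block halves resolution, doubles channels, and is pure", {
  cfg <- ocunet_config(dims = 2, levels = 2, base_channels = 8, alpha = 0.5,
                       convs_per_block = 2, aux_branches = 0)
  params <- ocunet_init(cfg, input_channels = 1, seed = 7)
  x <- multifreq_tensor(rand_array(c(1, 32, 32)), alpha = 0)
  out <- encoder_block_forward(x, params$enc[[1]])
  expect_identical(dim(out$high), c(4L, 16L, 16L))
  expect_identical(dim(out$low), c(4L, 8L, 8L))
  out2 <- encoder_block_forward(x, params$enc[[1]])
  expect_identical(out, out2)  # deterministic in inference mode
})

test_that("decoder block doubles resolution and validates skip shapes", {
  cfg <- ocunet_config(dims = 2, levels = 2, base_channels = 8, alpha = 0.5,
                       convs_per_block = 1, aux_branches = 0)
  params <- ocunet_init(cfg, input_channels = 1, seed = 8)
  # bottleneck-level feature: 32 channels at 8x8 (levels=2, base=8, input 32)
  x <- multifreq_tensor(rand_array(c(16, 8, 8)), rand_array(c(16, 4, 4)), 0.5)
  skip <- multifreq_tensor(rand_array(c(8, 16, 16)), rand_array(c(8, 8, 8)), 0.5)
  out <- decoder_block_forward(x, skip, params$dec[[2]])
  expect_identical(dim(out$high), c(8L, 16L, 16L))
  expect_identical(dim(out$low), c(8L, 8L, 8L))
  bad_skip <- multifreq_tensor(rand_array(c(8, 8, 8)), rand_array(c(8, 4, 4)), 0.5)
  expect_error(decoder_block_forward(x, bad_skip, params$dec[[2]]), "skip")
})

test_that("full forward pass emits normalized, reproducible probability maps", {
  cfg <- ocunet_config(dims = 2, levels = 2, base_channels = 4, alpha = 0.5,
                       convs_per_block = 1, aux_branches = 1)
  params <- ocunet_init(cfg, input_channels = 1, seed = 9)
  vol <- array(runif(32 * 32), c(32, 32))
  out <- ocunet_forward(vol, cfg, params)
  expect_identical(dim(out$main_prob), c(2L, 32L, 32L))
  sums <- apply(out$main_prob, 2:3, sum)
  expect_true(max(abs(sums - 1)) < 1e-6)
  expect_length(out$aux_probs, 1L)
  expect_identical(dim(out$aux_probs[[1]]), c(2L, 32L, 32L))
  out2 <- ocunet_forward(vol, cfg, params)
  expect_identical(out, out2)
  cfg0 <- ocunet_config(dims = 2, levels = 2, base_channels = 4, alpha = 0.5,
                        convs_per_block = 1, aux_branches = 0)
  p0 <- ocunet_init(cfg0, input_channels = 1, seed = 9)
  expect_length(ocunet_forward(vol, cfg0, p0)$aux_probs, 0L)
  expect_error(ocunet_forward(array(runif(30 * 30), c(30, 30)), cfg, params),
               "divisible")
})

test_that("an alpha=0 network is a plain U-Net with identical per-layer parameters", {
  mk <- function(a) ocunet_init(ocunet_config(dims = 2, levels = 3, base_channels = 8,
                                              alpha = a, convs_per_block = 2,
                                              aux_branches = 2),
                                input_channels = 1, seed = 21)
  k_oct <- ocunet:::.ocunet_kernels(mk(0.5))
  k_plain <- ocunet:::.ocunet_kernels(mk(0))
  expect_identical(names(k_oct), names(k_plain))
  for (nm in names(k_oct))
    expect_identical(param_count(k_oct[[nm]], include_bias = TRUE),
                     param_count(k_plain[[nm]], include_bias = TRUE))
  # alpha = 0 layers compute exactly a plain convolution given shared weights
  set.seed(22)
  x <- rand_array(c(8, 16, 16))
  kern <- octave_kernel(3, 8, 8, 0, 0, d = 2)
  got <- octave_conv_forward(multifreq_tensor(x, alpha = 0), kern)
  expect_identical(got$high, ocunet:::.conv_same(x, kern$weights$hh, kern$bias$high))
})

test_that("analytic gradients match finite differences across layer types", {
  set.seed(42)
  cfg <- ocunet_config(dims = 2, levels = 2, base_channels = 4, alpha = 0.5,
                       convs_per_block = 1, aux_branches = 1)
  p <- ocunet_init(cfg, 1, seed = 3)
  xs <- list(array(runif(256), c(1, 16, 16)), array(runif(256), c(1, 16, 16)))
  ys <- list(array(rbinom(256, 1, 0.2), c(16, 16)),
             array(rbinom(256, 1, 0.2), c(16, 16)))
  w <- loss_weights(main = 1, aux = 0.5)
  lg <- ocunet:::.batch_loss_grads(p, cfg, xs, ys, w, 1e-5)
  loss_at <- function(pp) ocunet:::.batch_loss_grads(pp, cfg, xs, ys, w, 1e-5)$loss
  eps <- 1e-6
  spots <- list(
    list(get = function(p) p$enc[[1]]$convs[[1]]$kernel$weights$hh[1, 1, 2, 2],
         set = function(p, v) { p$enc[[1]]$convs[[1]]$kernel$weights$hh[1, 1, 2, 2] <- v; p },
         g = lg$grads$enc[[1]]$convs[[1]]$weights$hh[1, 1, 2, 2]),
    list(get = function(p) p$bott$convs[[1]]$kernel$weights$hl[2, 1, 1, 1],
         set = function(p, v) { p$bott$convs[[1]]$kernel$weights$hl[2, 1, 1, 1] <- v; p },
         g = lg$grads$bott$convs[[1]]$weights$hl[2, 1, 1, 1]),
    list(get = function(p) p$dec[[1]]$tconv$weights$lh[1, 1, 2, 1],
         set = function(p, v) { p$dec[[1]]$tconv$weights$lh[1, 1, 2, 1] <- v; p },
         g = lg$grads$dec[[1]]$tconv$weights$lh[1, 1, 2, 1]),
    list(get = function(p) p$enc[[2]]$convs[[1]]$bn$low$gamma[1],
         set = function(p, v) { p$enc[[2]]$convs[[1]]$bn$low$gamma[1] <- v; p },
         g = lg$grads$enc[[2]]$convs[[1]]$bn$low$dgamma[1]),
    list(get = function(p) p$head$weights$hh[2, 1, 1, 1],
         set = function(p, v) { p$head$weights$hh[2, 1, 1, 1] <- v; p },
         g = lg$grads$head$weights$hh[2, 1, 1, 1]),
    list(get = function(p) p$aux[[1]]$weights$hh[1, 2, 1, 2],
         set = function(p, v) { p$aux[[1]]$weights$hh[1, 2, 1, 2] <- v; p },
         g = lg$grads$aux[[1]]$weights$hh[1, 2, 1, 2]))
  for (s in spots) {
    num <- (loss_at(s$set(p, s$get(p) + eps)) - loss_at(s$set(p, s$get(p) - eps))) / (2 * eps)
    expect_equal(s$g, num, tolerance = 1e-3)
  }
})

test_that("deep supervision feeds gradients into every encoder block", {
  set.seed(77)
  cfg <- ocunet_config(dims = 2, levels = 3, base_channels = 4, alpha = 0.5,
                       convs_per_block = 1, aux_branches = 2)
  p <- ocunet_init(cfg, 1, seed = 5)
  xs <- lapply(1:4, function(i) array(runif(32 * 32), c(1, 32, 32)))
  ys <- lapply(1:4, function(i) array(rbinom(32 * 32, 1, 0.15), c(32, 32)))
  lg <- ocunet:::.batch_loss_grads(p, cfg, xs, ys, loss_weights(), 1e-5)
  for (l in 1:3) for (i in seq_along(lg$grads$enc[[l]]$convs)) {
    gw <- lg$grads$enc[[l]]$convs[[i]]$weights
    for (nm in names(gw)) {
      if (is.null(gw[[nm]])) next
      expect_gt(sum(abs(gw[[nm]])), 0)
      expect_gt(mean(gw[[nm]] != 0), 0.5)
    }
    for (br in c("high", "low")) {
      gbn <- lg$grads$enc[[l]]$convs[[i]]$bn[[br]]
      if (!is.null(gbn)) expect_gt(sum(abs(gbn$dgamma)) + sum(abs(gbn$dbeta)), 0)
    }
  }
})
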