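test_that("channel splitting follows round-half-to-even and conserves totals", {
  expect_identical(split_channels(16, 0.5), c(high = 8L, low = 8L))
  expect_identical(split_channels(16, 0), c(high = 16L, low = 0L))
  expect_identical(split_channels(16, 1), c(high = 0L, low = 16L))
  expect_identical(split_channels(5, 0.5), c(high = 3L, low = 2L))  # round(2.5) = 2
  for (c_tot in 1:12) for (a in c(0, 0.25, 0.33, 0.5, 0.75, 1)) {
    s <- split_channels(c_tot, a)
    expect_identical(sum(s), as.integer(c_tot))
  }
  expect_error(split_channels(16, 1.2), "alpha")
  expect_error(split_channels(0, 0.5), "positive")
})

test_that("average pooling halves grids, preserves constants and block means", {
  x <- array(c(1, 3, 1, 3), c(1, 2, 2))  # column-major: rows (1,3)
  expect_equal(downsample_avg2(x), array(2, c(1, 1, 1)))
  cst <- array(7, c(3, 4, 6))
  expect_equal(downsample_avg2(cst), array(7, c(3, 2, 3)))
  # brute-force per-block mean oracle on a random 4x4
  set.seed(11)
  y <- rand_array(c(2, 4, 4))
  out <- downsample_avg2(y)
  for (ci in 1:2) for (i in 1:2) for (j in 1:2)
    expect_equal(out[ci, i, j],
                 mean(y[ci, (2 * i - 1):(2 * i), (2 * j - 1):(2 * j)]))
  # global sum preserved up to 2^d
  expect_equal(sum(out), sum(y) / 4)
  z <- rand_array(c(1, 2, 4, 2))
  expect_equal(sum(downsample_avg2(z)), sum(z) / 8)
  expect_error(downsample_avg2(rand_array(c(1, 3, 4))), "even")
})

test_that("nearest upsampling replicates cells and inverts pooling exactly", {
  expect_equal(upsample_nearest2(array(5, c(1, 1, 1))), array(5, c(1, 2, 2)))
  x <- array(1:4, c(1, 2, 2))
  up <- upsample_nearest2(x)
  expect_identical(dim(up), c(1L, 4L, 4L))
  for (i in 1:4) for (j in 1:4)
    expect_equal(up[1, i, j], x[1, ceiling(i / 2), ceiling(j / 2)])
  for (d in 2:3) {
    y <- rand_array(c(3, rep(4, d)))
    expect_equal(downsample_avg2(upsample_nearest2(y)), y)
  }
})

test_that("identity kernel and zero input reduce the octave convolution trivially", {
  set.seed(2)
  x <- rand_array(c(3, 7, 5))
  kern <- octave_kernel(3, 3, 3, 0, 0, d = 2, bias = FALSE, init = "zeros")
  for (ci in 1:3) kern$weights$hh[ci, ci, 2, 2] <- 1  # discrete delta
  out <- octave_conv_forward(multifreq_tensor(x, alpha = 0), kern)
  expect_equal(out$high, x)
  cs <- rand_case(d = 2, alpha_in = 0.5, alpha_out = 0.5, bias = FALSE)
  zero_in <- multifreq_tensor(array(0, dim(cs$input$high)),
                              array(0, dim(cs$input$low)), 0.5)
  zout <- octave_conv_forward(zero_in, cs$kernel)
  expect_equal(max(abs(zout$high)), 0)
  expect_equal(max(abs(zout$low)), 0)
})

test_that("forward operator matches the naive composition oracle", {
  set.seed(3)
  for (d in 2:3) for (a in c(0, 0.25, 0.5, 0.75)) for (k in c(1, 3)) {
    cs <- rand_case(d = d, alpha_in = a, alpha_out = a, k = k,
                    c_in = 4, c_out = 4, high = rep(if (d == 2) 8 else 4, d))
    got <- octave_conv_forward(cs$input, cs$kernel)
    want <- oracle_octave_conv(cs$input, cs$kernel)
    expect_lt(max_branch_diff(got, want) / rel_tol_scale(want), 1e-5)
  }
})

test_that("bias-free operator is linear and homogeneous", {
  set.seed(4)
  cs <- rand_case(d = 2, bias = FALSE)
  x2 <- multifreq_tensor(2 * cs$input$high, 2 * cs$input$low, 0.5)
  y1 <- octave_conv_forward(cs$input, cs$kernel)
  y2 <- octave_conv_forward(x2, cs$kernel)
  expect_equal(y2$high, 2 * y1$high, tolerance = 1e-12)
  expect_equal(y2$low, 2 * y1$low, tolerance = 1e-12)
  other <- rand_case(d = 2, bias = FALSE)
  mix <- multifreq_tensor(3 * cs$input$high - 0.5 * other$input$high,
                          3 * cs$input$low - 0.5 * other$input$low, 0.5)
  ym <- octave_conv_forward(mix, cs$kernel)
  yo <- octave_conv_forward(other$input, cs$kernel)
  expect_equal(ym$high, 3 * y1$high - 0.5 * yo$high, tolerance = 1e-10)
  expect_equal(ym$low, 3 * y1$low - 0.5 * yo$low, tolerance = 1e-10)
})

test_that("transpose operator doubles spatial dims and matches its oracle", {
  set.seed(5)
  for (d in 2:3) for (a in c(0, 0.5, 0.75)) {
    cs <- rand_case(d = d, alpha_in = a, alpha_out = a, k = 2,
                    c_in = 4, c_out = 6, high = rep(4, d), transpose = TRUE)
    got <- octave_transpose_conv_forward(cs$input, cs$kernel)
    want <- oracle_octave_transpose_conv(cs$input, cs$kernel)
    expect_lt(max_branch_diff(got, want) / rel_tol_scale(want), 1e-5)
    if (!is.null(got$high))
      expect_identical(dim(got$high)[-1], 2L * dim(cs$input$high)[-1])
    if (!is.null(got$low))
      expect_identical(dim(got$low)[-1], 2L * dim(cs$input$low)[-1])
  }
  # vanilla reduction: alpha = 0 equals one plain stride-2 transpose conv
  cs <- rand_case(d = 2, alpha_in = 0, alpha_out = 0, k = 2, c_in = 3,
                  c_out = 2, transpose = TRUE)
  got <- octave_transpose_conv_forward(cs$input, cs$kernel)
  plain <- ocunet:::.tconv2(cs$input$high, cs$kernel$weights$hh, cs$kernel$bias$high)
  expect_identical(got$high, plain)
})

test_that("parameter count equals the vanilla kernel for every alpha", {
  expect_identical(param_count(octave_kernel(3, 4, 8, 0.5, 0.5, d = 2)), 288L)
  expect_identical(param_count(octave_kernel(1, 1, 1, 0, 0, d = 2)), 1L)
  for (d in 2:3) for (k in c(1, 3)) for (cio in list(c(4, 8), c(16, 16), c(5, 7))) {
    counts <- sapply(c(0, 0.25, 0.5, 0.75, 1), function(a)
      param_count(octave_kernel(k, cio[1], cio[2], a, a, d = d)))
    expect_true(all(counts == k^d * cio[1] * cio[2]))
  }
  kb <- octave_kernel(3, 4, 8, 0.5, 0.5, d = 2, bias = TRUE)
  expect_identical(param_count(kb, include_bias = TRUE), 288L + 8L)
})

test_that("multiply-accumulate count decreases with alpha and matches cell counting", {
  sp <- c(8, 8)
  k0 <- octave_kernel(3, 8, 8, 0, 0, d = 2)
  expect_equal(flop_count(k0, sp), 9 * 8 * 8 * 64)
  # independent brute-force oracle: enumerate output cells per path
  count_oracle <- function(k, c_in, c_out, a, sp) {
    s_in <- split_channels(c_in, a); s_out <- split_channels(c_out, a)
    cells_h <- prod(sp); cells_l <- prod(sp %/% 2L)
    kd <- k^length(sp)
    cells_h * kd * s_in[["high"]] * s_out[["high"]] +
      cells_l * kd * s_in[["low"]] * s_out[["high"]] +
      cells_l * kd * s_in[["low"]] * s_out[["low"]] +
      cells_l * kd * s_in[["high"]] * s_out[["low"]]
  }
  k5 <- octave_kernel(3, 8, 8, 0.5, 0.5, d = 2)
  expect_equal(flop_count(k5, sp), count_oracle(3, 8, 8, 0.5, sp))
  expect_equal(flop_count(k5, sp) / flop_count(k0, sp), 0.4375)
  counts <- sapply(c(0, 0.25, 0.5, 0.75), function(a)
    flop_count(octave_kernel(3, 16, 16, a, a, d = 2), c(16, 16)))
  expect_true(all(diff(counts) < 0))
})

test_that("operator contracts reject malformed inputs", {
  cs <- rand_case(d = 2, alpha_in = 0.5, alpha_out = 0.5)
  wrong <- octave_kernel(3, 6, 4, 0.5, 0.5, d = 2)
  expect_error(octave_conv_forward(cs$input, wrong), "channels")
  expect_error(multifreq_tensor(rand_array(c(2, 8, 8)), rand_array(c(2, 3, 3))),
               "octave")
  expect_error(octave_kernel(4, 4, 4, 0.5, 0.5), "odd")
  odd <- multifreq_tensor(rand_array(c(4, 7, 7)), alpha = 0)
  k_mixed <- octave_kernel(3, 4, 4, 0, 0.5, d = 2)
  expect_error(octave_conv_forward(odd, k_mixed), "even")
})
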