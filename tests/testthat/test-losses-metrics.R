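test_that("soft Dice loss matches the closed form and its limiting cases", {
  set.seed(31)
  t10 <- array(rbinom(1000, 1, 0.3), c(10, 10, 10))
  expect_lt(soft_dice_loss(t10, t10), 1e-4)           # perfect overlap
  t2 <- array(c(rep(1, 40), rep(0, 60)), c(10, 10))
  expect_gt(soft_dice_loss(1 - t2, t2), 1 - 1e-3)     # zero overlap
  # direct formula evaluation oracle: p = 0.5 everywhere, half-foreground 4x4
  p <- array(0.5, c(4, 4))
  t4 <- array(c(rep(1, 8), rep(0, 8)), c(4, 4))
  s <- 1e-5
  want <- 1 - (2 * sum(p * t4) + s) / (sum(p) + sum(t4) + s)
  expect_equal(soft_dice_loss(p, t4, s), want)
  expect_equal(want, 1 - (8 + s) / (16 + s))
  expect_error(soft_dice_loss(array(0.5, c(4, 4)), array(0, c(5, 4))), "grid")
  expect_error(soft_dice_loss(array(2, c(2, 2)), array(0, c(2, 2))), "\\[0, 1\\]")
})

test_that("soft Dice loss converges to 1 - Dice as smoothing vanishes", {
  set.seed(32)
  pred <- array(rbinom(400, 1, 0.3), c(20, 20))
  truth <- array(rbinom(400, 1, 0.3), c(20, 20))
  hard <- compute_metrics(pred, truth)$dice
  expect_equal(soft_dice_loss(pred, truth, smooth = 1e-12), 1 - hard,
               tolerance = 1e-9)
})

test_that("the composite deep-supervision objective is a weighted sum", {
  set.seed(33)
  truth <- array(rbinom(256, 1, 0.25), c(16, 16))
  mk_prob <- function() {
    fg <- array(runif(256), c(16, 16))
    array(rbind(as.vector(1 - fg), as.vector(fg)), c(2, 16, 16))
  }
  outs <- list(main_prob = mk_prob(), aux_probs = list(mk_prob(), mk_prob()))
  w <- loss_weights(main = 1, aux = c(0.5, 0.25))
  fg <- function(p) array(matrix(p, 2)[2, ], c(16, 16))
  want <- soft_dice_loss(fg(outs$main_prob), truth) +
    0.5 * soft_dice_loss(fg(outs$aux_probs[[1]]), truth) +
    0.25 * soft_dice_loss(fg(outs$aux_probs[[2]]), truth)
  expect_equal(deep_supervised_loss(outs, truth, w), want)
  # linear in the weights
  w2 <- loss_weights(main = 2, aux = c(1, 0.5))
  expect_equal(deep_supervised_loss(outs, truth, w2),
               2 * deep_supervised_loss(outs, truth, w))
  # no aux branches: degenerates to the plain loss
  plain <- list(main_prob = outs$main_prob, aux_probs = list())
  expect_equal(deep_supervised_loss(plain, truth, loss_weights(aux = numeric(0))),
               soft_dice_loss(fg(outs$main_prob), truth))
  expect_error(deep_supervised_loss(outs, truth, loss_weights(aux = 0.5)), "aux")
  expect_error(loss_weights(main = 0), "main")
})

test_that("confusion counts agree with a per-voxel loop oracle", {
  truth <- array(0, c(10, 10)); truth[3:5, 4:6] <- 1  # 9 foreground... 3x3
  pred <- truth
  cc <- confusion_counts(pred, truth)
  expect_identical(c(cc$tp, cc$fp, cc$tn, cc$fn), c(9L, 0L, 91L, 0L))
  none <- array(0, c(10, 10))
  cc0 <- confusion_counts(none, truth)
  expect_identical(c(cc0$tp, cc0$fp), c(0L, 0L))
  set.seed(34)
  p <- array(rbinom(60, 1, 0.4), c(6, 10))
  t <- array(rbinom(60, 1, 0.3), c(6, 10))
  cc2 <- confusion_counts(p, t)
  tp <- fp <- tn <- fn <- 0L
  for (i in 1:6) for (j in 1:10) {
    if (p[i, j] == 1 && t[i, j] == 1) tp <- tp + 1L
    if (p[i, j] == 1 && t[i, j] == 0) fp <- fp + 1L
    if (p[i, j] == 0 && t[i, j] == 0) tn <- tn + 1L
    if (p[i, j] == 0 && t[i, j] == 1) fn <- fn + 1L
  }
  expect_identical(c(cc2$tp, cc2$fp, cc2$tn, cc2$fn), c(tp, fp, tn, fn))
  expect_identical(cc2$tp + cc2$fp + cc2$tn + cc2$fn, 60L)
  expect_error(confusion_counts(p, array(0, c(10, 6))), "grid")
})

test_that("metrics match direct substitution into their defining ratios", {
  # masks realizing tp=3, fp=1, fn=2, tn=94 on a 10x10 grid
  truth <- array(0, c(10, 10)); truth[1, 1:5] <- 1
  pred <- array(0, c(10, 10)); pred[1, 1:3] <- 1; pred[2, 1] <- 1
  m <- compute_metrics(pred, truth)
  expect_identical(c(m$tp, m$fp, m$fn, m$tn), c(3L, 1L, 2L, 94L))
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$accuracy, 0.97)
  expect_equal(m$specificity, 94 / 95)
  expect_equal(m$dice, 2 * 3 / (2 * 3 + 1 + 2))
  # identical masks overlap completely
  expect_equal(compute_metrics(truth, truth)$dice, 1)
  # disjoint nonempty masks share nothing
  a <- array(0, c(8, 8)); a[1:2, 1:2] <- 1
  b <- array(0, c(8, 8)); b[5:6, 5:6] <- 1
  expect_equal(compute_metrics(a, b)$dice, 0)
})

test_that("Dice is symmetric, bounded, and equals its confusion identity", {
  set.seed(35)
  for (r in 1:25) {
    p <- array(rbinom(64, 1, runif(1)), c(8, 8))
    t <- array(rbinom(64, 1, runif(1)), c(8, 8))
    m1 <- compute_metrics(p, t); m2 <- compute_metrics(t, p)
    expect_equal(m1$dice, m2$dice)
    expect_gte(m1$dice, 0); expect_lte(m1$dice, 1)
    # count-identity on binary masks, exact integer arithmetic
    inter <- sum(p * t)
    den <- sum(p) + sum(t)
    want <- if (den == 0) 1 else 2 * inter / den
    expect_equal(m1$dice, want)
  }
})

test_that("empty-denominator metrics follow the agreed convention", {
  e <- array(0, c(5, 5))
  m <- compute_metrics(e, e)
  expect_equal(m$dice, 1)        # both empty: trivial agreement
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$accuracy, 1)
  f <- array(0, c(5, 5)); f[1, 1] <- 1
  m2 <- compute_metrics(e, f)    # empty prediction, nonempty truth
  expect_equal(m2$dice, 0)
  expect_equal(m2$precision, 0)
  expect_equal(m2$recall, 0)
  ones <- array(1, c(5, 5))
  m3 <- compute_metrics(ones, ones)  # no negatives anywhere
  expect_equal(m3$specificity, 1)
  expect_equal(m3$dice, 1)
})
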