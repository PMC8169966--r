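# Pure-R reference primitives: shift-and-add convolution and index-based
# resampling. These share no code with the C++ kernels and exist so the
# naive-composition oracles (and the test suite) have an independent path
# to the same maps. Adequate for the small grids used in testing.

.r_conv_same <- function(x, w, bias = NULL) {
  ci <- dim(x)[1L]; sp <- .spatial_dims(x); d <- length(sp)
  co <- dim(w)[1L]; k <- dim(w)[3L]
  half <- (k - 1L) %/% 2L
  ymat <- matrix(0, co, prod(sp))
  offsets <- as.matrix(expand.grid(rep(list(seq_len(k) - 1L - half), d)))
  for (r in seq_len(nrow(offsets))) {
    off <- offsets[r, ]
    tgt <- src <- vector("list", d)
    ok <- TRUE
    for (a in seq_len(d)) {
      t_a <- seq.int(max(1L, 1L - off[a]), min(sp[a], sp[a] - off[a]))
      if (length(t_a) == 0L) { ok <- FALSE; break }
      tgt[[a]] <- t_a
      src[[a]] <- t_a + off[a]
    }
    if (!ok) next
    xs <- array(0, c(ci, sp))
    xs <- .slab_assign(xs, tgt, .slab(x, src))
    w_off <- do.call(`[`, c(list(w), list(TRUE, TRUE), as.list(off + 1L + half), list(drop = FALSE)))
    ymat <- ymat + matrix(w_off, co, ci) %*% matrix(xs, ci)
  }
  if (!is.null(bias)) ymat <- ymat + bias
  array(ymat, c(co, sp))
}

.r_avgpool2 <- function(x) {
  sp <- .spatial_dims(x); d <- length(sp)
  out <- array(0, c(dim(x)[1L], sp %/% 2L))
  corners <- as.matrix(expand.grid(rep(list(0:1), d)))
  for (r in seq_len(nrow(corners))) {
    idx <- lapply(seq_len(d), function(a) seq.int(1L + corners[r, a], sp[a], by = 2L))
    out <- out + .slab(x, idx)
  }
  out / 2^d
}

.r_upsample_nearest2 <- function(x) {
  sp <- .spatial_dims(x); d <- length(sp)
  idx <- lapply(sp, function(s) rep(seq_len(s), each = 2L))
  .slab(x, idx)
}

# stride-2 transpose convolution with extent-2 kernels, by direct scatter
.r_tconv2 <- function(x, w, bias = NULL) {
  ci <- dim(x)[1L]; sp <- .spatial_dims(x); d <- length(sp)
  co <- dim(w)[1L]
  out_sp <- 2L * sp
  y <- array(if (is.null(bias)) 0 else rep(bias, prod(out_sp)), c(co, out_sp))
  corners <- as.matrix(expand.grid(rep(list(0:1), d)))
  xmat <- matrix(x, ci)
  for (r in seq_len(nrow(corners))) {
    w_off <- do.call(`[`, c(list(w), list(TRUE, TRUE), as.list(corners[r, ] + 1L), list(drop = FALSE)))
    contrib <- array(matrix(w_off, co, ci) %*% xmat, c(co, sp))
    idx <- lapply(seq_len(d), function(a) seq.int(1L + corners[r, a], out_sp[a], by = 2L))
    y <- .slab_assign(y, idx, .slab(y, idx) + contrib)
  }
  y
}
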