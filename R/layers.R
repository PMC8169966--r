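# Internal batched layer primitives. A "batch" is a list of channel-first
# arrays (one per sample); multifrequency batches are lists of
# list(high=, low=) pairs. Batch-norm statistics are computed jointly over
# batch and spatial positions, per channel.

.bn_state <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c), mean = numeric(c), var = rep(1, c))
}

.bn_eps <- 1e-5
.bn_momentum <- 0.1

# xs: list of (c, spatial...) arrays -> list(out, cache, state)
.bn_fwd <- function(xs, st, training) {
  c <- dim(xs[[1L]])[1L]
  dims <- lapply(xs, dim)
  M <- do.call(cbind, lapply(xs, function(x) matrix(x, nrow = c)))
  if (training) {
    m <- rowMeans(M)
    v <- rowMeans(M * M) - m * m
    v[v < 0] <- 0
    st$mean <- (1 - .bn_momentum) * st$mean + .bn_momentum * m
    st$var <- (1 - .bn_momentum) * st$var + .bn_momentum * v
  } else {
    m <- st$mean; v <- st$var
  }
  inv_std <- 1 / sqrt(v + .bn_eps)
  xhat <- (M - m) * inv_std
  Y <- st$gamma * xhat + st$beta
  ncols <- vapply(dims, function(d) prod(d[-1L]), numeric(1))
  ends <- cumsum(ncols); starts <- c(1, head(ends, -1) + 1)
  out <- lapply(seq_along(xs), function(i) array(Y[, starts[i]:ends[i]], dims[[i]]))
  list(out = out,
       cache = list(xhat = xhat, inv_std = inv_std, gamma = st$gamma,
                    dims = dims, starts = starts, ends = ends, training = training),
       state = st)
}

# dys: list of gradient arrays -> list(dx = list, dgamma, dbeta)
.bn_bwd <- function(dys, cache) {
  c <- length(cache$gamma)
  G <- do.call(cbind, lapply(dys, function(g) matrix(g, nrow = c)))
  xhat <- cache$xhat
  dgamma <- rowSums(G * xhat)
  dbeta <- rowSums(G)
  if (cache$training) {
    n <- ncol(G)
    dxhat <- G * cache$gamma
    dX <- cache$inv_std / n * (n * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  } else {
    dX <- G * (cache$gamma * cache$inv_std)
  }
  dx <- lapply(seq_along(dys), function(i)
    array(dX[, cache$starts[i]:cache$ends[i]], cache$dims[[i]]))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

.relu_fwd <- function(xs) {
  masks <- lapply(xs, function(x) x > 0)
  list(out = lapply(seq_along(xs), function(i) xs[[i]] * masks[[i]]), masks = masks)
}

.relu_bwd <- function(dys, masks) {
  lapply(seq_along(dys), function(i) dys[[i]] * masks[[i]])
}

# channel-wise softmax on a (nc, spatial...) array
.softmax <- function(z) {
  nc <- dim(z)[1L]
  M <- matrix(z, nrow = nc)
  mx <- do.call(pmax, c(asplit(M, 1L), list(na.rm = FALSE)))
  E <- exp(M - rep(mx, each = nc))
  P <- E / rep(colSums(E), each = nc)
  array(P, dim(z))
}

# adjoint: given probs p and dL/dp, return dL/dlogits
.softmax_bwd <- function(p, dp) {
  nc <- dim(p)[1L]
  P <- matrix(p, nrow = nc); G <- matrix(dp, nrow = nc)
  s <- colSums(P * G)
  array(P * (G - rep(s, each = nc)), dim(p))
}

# ---- multifrequency batch helpers ---------------------------------------

.mf_map <- function(batch, f) {
  lapply(batch, function(x) list(
    high = if (is.null(x$high)) NULL else f(x$high),
    low = if (is.null(x$low)) NULL else f(x$low)))
}

.mf_pool_fwd <- function(batch) .mf_map(batch, downsample_avg2)

.mf_pool_bwd <- function(dbatch) {
  lapply(dbatch, function(g) list(
    high = if (is.null(g$high)) NULL else .avgpool2_adj(g$high, .ndim_spatial(g$high)),
    low = if (is.null(g$low)) NULL else .avgpool2_adj(g$low, .ndim_spatial(g$low))))
}

.cat_channels <- function(a, b) {
  ca <- dim(a)[1L]; cb <- dim(b)[1L]; sp <- .spatial_dims(a)
  array(rbind(matrix(a, ca), matrix(b, cb)), c(ca + cb, sp))
}

.split_channels_arr <- function(x, c1) {
  cx <- dim(x)[1L]; sp <- .spatial_dims(x)
  M <- matrix(x, cx)
  list(array(M[seq_len(c1), , drop = FALSE], c(c1, sp)),
       array(M[(c1 + 1L):cx, , drop = FALSE], c(cx - c1, sp)))
}

.mf_concat <- function(batch_a, batch_b) {
  lapply(seq_along(batch_a), function(i) {
    a <- batch_a[[i]]; b <- batch_b[[i]]
    list(high = if (is.null(a$high)) b$high else if (is.null(b$high)) a$high
                else .cat_channels(a$high, b$high),
         low = if (is.null(a$low)) b$low else if (is.null(b$low)) a$low
               else .cat_channels(a$low, b$low))
  })
}

.mf_concat_bwd <- function(dbatch, c1_high, c1_low) {
  da <- db <- vector("list", length(dbatch))
  for (i in seq_along(dbatch)) {
    g <- dbatch[[i]]
    if (is.null(g$high)) { gh_a <- gh_b <- NULL }
    else { s <- .split_channels_arr(g$high, c1_high); gh_a <- s[[1L]]; gh_b <- s[[2L]] }
    if (is.null(g$low)) { gl_a <- gl_b <- NULL }
    else { s <- .split_channels_arr(g$low, c1_low); gl_a <- s[[1L]]; gl_b <- s[[2L]] }
    da[[i]] <- list(high = gh_a, low = gl_a)
    db[[i]] <- list(high = gh_b, low = gl_b)
  }
  list(da, db)
}

.mf_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  lapply(seq_along(a), function(i) list(
    high = if (is.null(a[[i]]$high)) b[[i]]$high
           else if (is.null(b[[i]]$high)) a[[i]]$high else a[[i]]$high + b[[i]]$high,
    low = if (is.null(a[[i]]$low)) b[[i]]$low
          else if (is.null(b[[i]]$low)) a[[i]]$low else a[[i]]$low + b[[i]]$low))
}

# ---- octave conv batched forward/backward --------------------------------

.oct_fwd_batch <- function(batch, kernel) {
  fwd <- if (kernel$transpose) octave_transpose_conv_forward else octave_conv_forward
  lapply(batch, function(x) {
    y <- fwd(multifreq_tensor(x$high, x$low, alpha = kernel$alpha_in), kernel)
    list(high = y$high, low = y$low)
  })
}

# accumulates weight/bias grads over the batch; returns input grads
.oct_bwd_batch <- function(batch_in, kernel, dbatch) {
  bwd <- if (kernel$transpose) .octave_tconv_backward else .octave_conv_backward
  dw_tot <- list(hh = NULL, lh = NULL, ll = NULL, hl = NULL)
  db_tot <- list(high = NULL, low = NULL)
  dxs <- vector("list", length(batch_in))
  add <- function(a, b) if (is.null(a)) b else if (is.null(b)) a else a + b
  for (i in seq_along(batch_in)) {
    r <- bwd(batch_in[[i]], kernel, dbatch[[i]])
    dxs[[i]] <- r$d_input
    for (nm in names(dw_tot)) dw_tot[[nm]] <- add(dw_tot[[nm]], r$d_weights[[nm]])
    for (nm in names(db_tot)) db_tot[[nm]] <- add(db_tot[[nm]], r$d_bias[[nm]])
  }
  list(dx = dxs, d_weights = dw_tot, d_bias = db_tot)
}
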