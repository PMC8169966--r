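#' Configure an OCunet segmentation network
#'
#' OCunet is a U-Net-shaped encoder-decoder built from octave convolutions:
#' every hidden feature map carries a high-frequency branch and a
#' low-frequency branch one octave below it. Encoder blocks apply
#' `convs_per_block` octave convolutions (each followed by batch
#' normalization and rectification) and then halve both branches by average
#' pooling, doubling the channel count per level; the decoder mirrors the
#' encoder with stride-2 octave transpose convolutions and branch-wise skip
#' concatenation. The network input enters as a single-frequency signal
#' (`alpha_in = 0` on the first layer) and the prediction head emits a
#' full-resolution-only probability map (`alpha_out = 0`), softmax over
#' `num_classes`. Deep supervision taps (up to two) attach auxiliary
#' prediction heads to the two decoder levels just below full resolution.
#'
#' @param dims Spatial dimensionality, 2 or 3.
#' @param levels Number of down-sampling stages (>= 1).
#' @param base_channels Channels at level 1 (>= 2); doubles per level.
#' @param alpha Low-frequency channel fraction of all hidden layers, in
#'   `[0, 1)`. `alpha = 0` reduces the network to a plain U-Net.
#' @param convs_per_block Convolutions per encoder/decoder block.
#' @param aux_branches Number of deep-supervision heads, 0, 1 or 2
#'   (requires `levels > aux_branches`).
#' @param num_classes Number of output classes (2: tumor vs background).
#' @return An object of class `ocunet_config`.
#' @export
ocunet_config <- function(dims = 2, levels = 4, base_channels = 32, alpha = 0.5,
                          convs_per_block = 2, aux_branches = 2, num_classes = 2) {
  if (!dims %in% c(2L, 3L)) .stopf("dims must be 2 or 3")
  if (!.is_count(levels) || levels < 1) .stopf("levels must be >= 1")
  if (!.is_count(base_channels) || base_channels < 2) .stopf("base_channels must be >= 2")
  if (alpha < 0 || alpha >= 1) .stopf("alpha must be in [0, 1)")
  if (!.is_count(convs_per_block) || convs_per_block < 1) .stopf("convs_per_block must be >= 1")
  if (!aux_branches %in% 0:2) .stopf("aux_branches must be 0, 1 or 2")
  if (aux_branches >= levels)
    .stopf("aux_branches = %d needs levels > %d (taps sit below full resolution)",
           aux_branches, aux_branches)
  structure(list(dims = as.integer(dims), levels = as.integer(levels),
                 base_channels = as.integer(base_channels), alpha = alpha,
                 convs_per_block = as.integer(convs_per_block),
                 aux_branches = as.integer(aux_branches),
                 num_classes = as.integer(num_classes)),
            class = "ocunet_config")
}

#' @export
print.ocunet_config <- function(x, ...) {
  cat(sprintf("<ocunet_config> %dD, levels=%d, base=%d, alpha=%g, convs/block=%d, aux=%d, classes=%d\n",
              x$dims, x$levels, x$base_channels, x$alpha, x$convs_per_block,
              x$aux_branches, x$num_classes))
  invisible(x)
}

# required divisor of every input spatial dim: one extra octave below the
# deepest level so the bottleneck low branch is still a whole grid
.legal_multiple <- function(levels) as.integer(2^(levels + 1L))

#' Tabulate per-level branch shapes of an OCunet
#'
#' Returns, for every encoder level, the bottleneck and every decoder
#' level, the channel count and spatial dims of the high- and low-frequency
#' branches. Decoder shapes mirror encoder shapes exactly (required for
#' skip concatenation). Errors when the input grid is not divisible by
#' `2^(levels + 1)`.
#'
#' @param config An [ocunet_config()].
#' @param input_spatial Integer vector of input spatial dims.
#' @return A tibble with columns `stage`, `level`, `branch`, `channels`,
#'   and `spatial` (list column of integer dims).
#' @export
plan_shapes <- function(config, input_spatial) {
  stopifnot(inherits(config, "ocunet_config"))
  if (length(input_spatial) != config$dims)
    .stopf("input_spatial must have %d dims", config$dims)
  m <- .legal_multiple(config$levels)
  if (any(input_spatial %% m != 0))
    .stopf("input spatial dims (%s) must be divisible by %d (= 2^(levels+1)); pad first",
           paste(input_spatial, collapse = "x"), m)
  a <- config$alpha
  rows <- list()
  add <- function(stage, level, c_total, high_sp) {
    split <- split_channels(c_total, a)
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      stage = stage, level = level, branch = "high",
      channels = split[["high"]], spatial = list(as.integer(high_sp)))
    if (split[["low"]] > 0L)
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        stage = stage, level = level, branch = "low",
        channels = split[["low"]], spatial = list(as.integer(high_sp %/% 2L)))
  }
  for (l in seq_len(config$levels))
    add("encoder", l, config$base_channels * 2L^(l - 1L), input_spatial %/% 2L^(l - 1L))
  add("bottleneck", config$levels + 1L, config$base_channels * 2L^config$levels,
      input_spatial %/% 2L^config$levels)
  for (l in rev(seq_len(config$levels)))
    add("decoder", l, config$base_channels * 2L^(l - 1L), input_spatial %/% 2L^(l - 1L))
  do.call(rbind, rows)
}

# channel entering encoder level l
.enc_in_channels <- function(config, l, input_channels) {
  if (l == 1L) input_channels else config$base_channels * 2L^(l - 2L)
}

#' Initialize OCunet parameters
#'
#' Creates all kernels (zero-mean Gaussian weights, sd `init_sd`), biases
#' and batch-normalization states of an OCunet. Reproducible given `seed`.
#'
#' @param config An [ocunet_config()].
#' @param input_channels Channels of the input volume (1 for CT).
#' @param seed Optional RNG seed for the Gaussian initializer.
#' @param init_sd Weight initialization standard deviation.
#' @return An object of class `ocunet_params`.
#' @export
ocunet_init <- function(config, input_channels = 1, seed = NULL, init_sd = 0.01) {
  stopifnot(inherits(config, "ocunet_config"))
  if (!is.null(seed)) set.seed(seed)
  a <- config$alpha; d <- config$dims; b <- config$base_channels
  L <- config$levels; cpb <- config$convs_per_block

  conv_layer <- function(c_in, c_out, alpha_in, alpha_out) {
    kern <- octave_kernel(3, c_in, c_out, alpha_in, alpha_out, d = d,
                          bias = FALSE, init_sd = init_sd)
    split <- split_channels(c_out, alpha_out)
    list(kernel = kern,
         bn = list(high = if (split[["high"]] > 0L) .bn_state(split[["high"]]),
                   low = if (split[["low"]] > 0L) .bn_state(split[["low"]])))
  }
  block <- function(c_in, c_out, alpha_first) {
    lapply(seq_len(cpb), function(i)
      conv_layer(if (i == 1L) c_in else c_out, c_out,
                 if (i == 1L) alpha_first else a, a))
  }

  enc <- lapply(seq_len(L), function(l)
    list(convs = block(.enc_in_channels(config, l, input_channels),
                       b * 2L^(l - 1L), if (l == 1L) 0 else a)))
  bott <- list(convs = block(b * 2L^(L - 1L), b * 2L^L, a))
  dec <- vector("list", L)
  for (l in rev(seq_len(L))) {
    c_in <- if (l == L) b * 2L^L else b * 2L^l
    c_out <- b * 2L^(l - 1L)
    dec[[l]] <- list(
      tconv = octave_kernel(2, c_in, c_out, a, a, d = d, bias = TRUE,
                            init_sd = init_sd, transpose = TRUE),
      convs = block(2L * c_out, c_out, a))
  }
  head <- octave_kernel(1, b, config$num_classes, a, 0, d = d, bias = TRUE,
                        init_sd = init_sd)
  aux <- if (config$aux_branches > 0)
    lapply(seq_len(config$aux_branches), function(j)
      octave_kernel(2, b * 2L^j, config$num_classes, a, 0, d = d, bias = TRUE,
                    init_sd = init_sd, transpose = TRUE))
  else list()

  structure(list(enc = enc, bott = bott, dec = dec, head = head, aux = aux,
                 input_channels = as.integer(input_channels)),
            class = "ocunet_params")
}

# total learnable parameter count (kernels + biases + BN scale/shift)
.ocunet_n_params <- function(params) {
  n <- 0L
  walk <- function(x) {
    if (inherits(x, "octave_kernel")) n <<- n + param_count(x, include_bias = TRUE)
    else if (is.list(x)) {
      if (!is.null(x$gamma)) n <<- n + length(x$gamma) + length(x$beta)
      else lapply(x, walk)
    }
  }
  walk(params[c("enc", "bott", "dec", "head", "aux")])
  n
}

# list of all kernels in network order, for layerwise comparisons
.ocunet_kernels <- function(params) {
  out <- list()
  grab <- function(x, nm) {
    if (inherits(x, "octave_kernel")) out[[nm]] <<- x
    else if (is.list(x) && is.null(x$gamma))
      for (i in seq_along(x)) {
        nmi <- if (!is.null(names(x))) names(x)[i] else as.character(i)
        grab(x[[i]], paste(nm, nmi, sep = "."))
      }
  }
  grab(params[c("enc", "bott", "dec", "head", "aux")], "net")
  out
}

# ---- batched conv blocks -------------------------------------------------

.convs_fwd <- function(batch, convs, training, keep_cache) {
  caches <- if (keep_cache) vector("list", length(convs))
  for (i in seq_along(convs)) {
    cl <- convs[[i]]
    conv_in <- batch
    out <- .oct_fwd_batch(batch, cl$kernel)
    bn_cache <- list(high = NULL, low = NULL)
    for (br in c("high", "low")) {
      if (!is.null(cl$bn[[br]])) {
        r <- .bn_fwd(lapply(out, `[[`, br), cl$bn[[br]], training)
        convs[[i]]$bn[[br]] <- r$state
        for (s in seq_along(out)) out[[s]][[br]] <- r$out[[s]]
        bn_cache[[br]] <- r$cache
      }
    }
    masks <- lapply(out, function(x) list(
      high = if (!is.null(x$high)) x$high > 0,
      low = if (!is.null(x$low)) x$low > 0))
    out <- lapply(seq_along(out), function(s) list(
      high = if (!is.null(out[[s]]$high)) out[[s]]$high * masks[[s]]$high,
      low = if (!is.null(out[[s]]$low)) out[[s]]$low * masks[[s]]$low))
    if (keep_cache) caches[[i]] <- list(conv_in = conv_in, bn = bn_cache, masks = masks)
    batch <- out
  }
  list(out = batch, params = convs, cache = caches)
}

.convs_bwd <- function(dbatch, convs, caches) {
  grads <- vector("list", length(convs))
  for (i in rev(seq_along(convs))) {
    cl <- convs[[i]]; ch <- caches[[i]]
    dbatch <- lapply(seq_along(dbatch), function(s) list(
      high = if (!is.null(dbatch[[s]]$high)) dbatch[[s]]$high * ch$masks[[s]]$high,
      low = if (!is.null(dbatch[[s]]$low)) dbatch[[s]]$low * ch$masks[[s]]$low))
    bn_g <- list(high = NULL, low = NULL)
    for (br in c("high", "low")) {
      if (!is.null(ch$bn[[br]])) {
        r <- .bn_bwd(lapply(dbatch, `[[`, br), ch$bn[[br]])
        for (s in seq_along(dbatch)) dbatch[[s]][[br]] <- r$dx[[s]]
        bn_g[[br]] <- list(dgamma = r$dgamma, dbeta = r$dbeta)
      }
    }
    r <- .oct_bwd_batch(ch$conv_in, cl$kernel, dbatch)
    grads[[i]] <- list(weights = r$d_weights, bias = r$d_bias, bn = bn_g)
    dbatch <- r$dx
  }
  list(dx = dbatch, grads = grads)
}

# ---- full network forward ------------------------------------------------

.take_channel <- function(p, ch) {
  nc <- dim(p)[1L]; sp <- .spatial_dims(p)
  array(matrix(p, nc)[ch, ], sp)
}

.forward_net <- function(params, config, xs, training = FALSE, keep_cache = FALSE) {
  L <- config$levels
  batch <- lapply(xs, function(x) list(high = x, low = NULL))
  cache <- list(enc = vector("list", L), dec = vector("list", L), aux = list())
  for (l in seq_len(L)) {
    r <- .convs_fwd(batch, params$enc[[l]]$convs, training, keep_cache)
    params$enc[[l]]$convs <- r$params
    cache$enc[[l]] <- list(convs = r$cache, prepool = r$out)
    batch <- .mf_pool_fwd(r$out)
  }
  r <- .convs_fwd(batch, params$bott$convs, training, keep_cache)
  params$bott$convs <- r$params
  cache$bott <- r$cache
  batch <- r$out
  dec_out <- vector("list", L)
  for (l in rev(seq_len(L))) {
    dp <- params$dec[[l]]
    if (keep_cache) cache$dec[[l]]$tconv_in <- batch
    up <- .oct_fwd_batch(batch, dp$tconv)
    merged <- .mf_concat(up, cache$enc[[l]]$prepool)
    r <- .convs_fwd(merged, dp$convs, training, keep_cache)
    params$dec[[l]]$convs <- r$params
    if (keep_cache) cache$dec[[l]]$convs <- r$cache
    batch <- r$out
    dec_out[[l]] <- batch
  }
  if (keep_cache) cache$head_in <- batch
  logits <- .oct_fwd_batch(batch, params$head)
  probs <- lapply(logits, function(z) .softmax(z$high))
  aux_probs <- list()
  if (config$aux_branches > 0) {
    for (j in seq_len(config$aux_branches)) {
      tap <- dec_out[[j + 1L]]
      az <- lapply(.oct_fwd_batch(tap, params$aux[[j]]), `[[`, "high")
      if (j > 1L) for (t in seq_len(j - 1L)) az <- lapply(az, upsample_nearest2)
      aux_probs[[j]] <- lapply(az, .softmax)
      if (keep_cache) cache$aux[[j]] <- list(tap = tap)
    }
  }
  if (keep_cache) {
    cache$probs <- probs
    cache$aux_probs <- aux_probs
  }
  list(probs = probs, aux_probs = aux_probs, params = params,
       cache = if (keep_cache) cache else NULL)
}

# d_main, d_aux: per-sample lists of dL/dprob arrays (nc, spatial at full res)
.backward_net <- function(params, config, cache, d_main, d_aux) {
  L <- config$levels
  n <- length(d_main)
  grads <- list(enc = vector("list", L), bott = NULL, dec = vector("list", L),
                head = NULL, aux = vector("list", config$aux_branches))

  dlogits <- lapply(seq_len(n), function(s) list(
    high = .softmax_bwd(cache$probs[[s]], d_main[[s]]), low = NULL))
  r <- .oct_bwd_batch(cache$head_in, params$head, dlogits)
  grads$head <- list(weights = r$d_weights, bias = r$d_bias)
  d <- r$dx

  d_tap <- vector("list", L + 1L)
  if (config$aux_branches > 0) {
    for (j in seq_len(config$aux_branches)) {
      dz <- lapply(seq_len(n), function(s)
        .softmax_bwd(cache$aux_probs[[j]][[s]], d_aux[[j]][[s]]))
      if (j > 1L) {
        dd <- .ndim_spatial(dz[[1L]])
        for (t in seq_len(j - 1L)) dz <- lapply(dz, .upsample2_adj, d = dd)
      }
      dz <- lapply(dz, function(g) list(high = g, low = NULL))
      r <- .oct_bwd_batch(cache$aux[[j]]$tap, params$aux[[j]], dz)
      grads$aux[[j]] <- list(weights = r$d_weights, bias = r$d_bias)
      d_tap[[j + 1L]] <- r$dx
    }
  }

  skip_grads <- vector("list", L)
  for (l in seq_len(L)) {
    if (l >= 2L && !is.null(d_tap[[l]])) d <- .mf_add(d, d_tap[[l]])
    dp <- params$dec[[l]]
    r <- .convs_bwd(d, dp$convs, cache$dec[[l]]$convs)
    grads$dec[[l]]$convs <- r$grads
    spl <- dp$tconv$split_out
    parts <- .mf_concat_bwd(r$dx, spl[["high"]], spl[["low"]])
    skip_grads[[l]] <- parts[[2L]]
    rt <- .oct_bwd_batch(cache$dec[[l]]$tconv_in, dp$tconv, parts[[1L]])
    grads$dec[[l]]$tconv <- list(weights = rt$d_weights, bias = rt$d_bias)
    d <- rt$dx
  }

  r <- .convs_bwd(d, params$bott$convs, cache$bott)
  grads$bott <- list(convs = r$grads)
  d <- r$dx
  for (l in rev(seq_len(L))) {
    d <- .mf_add(.mf_pool_bwd(d), skip_grads[[l]])
    r <- .convs_bwd(d, params$enc[[l]]$convs, cache$enc[[l]]$convs)
    grads$enc[[l]] <- list(convs = r$grads)
    d <- r$dx
  }
  grads
}

# ---- exported block and network forward ----------------------------------

#' Run one octave encoder block
#'
#' Applies the block's octave convolutions (each followed by batch
#' normalization and rectification) and then halves both branches by
#' average pooling; the channel count doubles across the block.
#'
#' @param x A [multifreq_tensor()].
#' @param params One element of `ocunet_params$enc` (a list with `convs`).
#' @param training Use batch statistics (`TRUE`) or running statistics.
#' @return A [multifreq_tensor()] at half resolution.
#' @export
encoder_block_forward <- function(x, params, training = FALSE) {
  r <- .convs_fwd(list(list(high = x$high, low = x$low)), params$convs,
                  training, keep_cache = FALSE)
  pooled <- .mf_pool_fwd(r$out)[[1L]]
  multifreq_tensor(pooled$high, pooled$low)
}

#' Run one octave decoder block
#'
#' Doubles both branches' spatial dims with a stride-2 octave transpose
#' convolution, concatenates the skip tensor branch-wise (high with high,
#' low with low), and refines with the block's octave convolutions.
#'
#' @param x A [multifreq_tensor()] from the previous (deeper) stage.
#' @param skip The matching encoder feature (pre-pooling).
#' @param params One element of `ocunet_params$dec` (fields `tconv`, `convs`).
#' @param training Use batch statistics (`TRUE`) or running statistics.
#' @return A [multifreq_tensor()] at twice the input resolution.
#' @export
decoder_block_forward <- function(x, skip, params, training = FALSE) {
  up <- .oct_fwd_batch(list(list(high = x$high, low = x$low)), params$tconv)
  expect_sp <- .mf_spatial(list(high = up[[1L]]$high, low = up[[1L]]$low))
  if (!identical(as.integer(.mf_spatial(skip)), as.integer(expect_sp)))
    .stopf("skip spatial dims (%s) do not match upsampled dims (%s)",
           paste(.mf_spatial(skip), collapse = "x"), paste(expect_sp, collapse = "x"))
  merged <- .mf_concat(up, list(list(high = skip$high, low = skip$low)))
  r <- .convs_fwd(merged, params$convs, training, keep_cache = FALSE)
  multifreq_tensor(r$out[[1L]]$high, r$out[[1L]]$low)
}

#' Full OCunet forward pass
#'
#' Runs a normalized volume through the network and returns softmax
#' probability maps: the main prediction at input resolution plus one map
#' per deep-supervision branch, each also at input resolution.
#'
#' @param volume A [seg_volume()] or a plain spatial array (values in
#'   `[0, 1]`, dims divisible by `2^(levels+1)`).
#' @param config The [ocunet_config()] used to build `params`.
#' @param params An [ocunet_init()] parameter set.
#' @param training Use batch statistics in normalization layers.
#' @return A list of class `ocunet_outputs` with `main_prob` (array
#'   `(num_classes, spatial...)`) and `aux_probs` (list of such arrays,
#'   length `aux_branches`).
#' @export
ocunet_forward <- function(volume, config, params, training = FALSE) {
  stopifnot(inherits(config, "ocunet_config"), inherits(params, "ocunet_params"))
  vox <- if (inherits(volume, "seg_volume")) volume$voxels else volume
  if (length(dim(vox)) == config$dims) dim(vox) <- c(1L, dim(vox))
  if (dim(vox)[1L] != params$input_channels)
    .stopf("volume has %d channels; params expect %d", dim(vox)[1L], params$input_channels)
  sp <- .spatial_dims(vox)
  m <- .legal_multiple(config$levels)
  if (any(sp %% m != 0))
    .stopf("input spatial dims (%s) must be divisible by %d; use pad_to_legal()",
           paste(sp, collapse = "x"), m)
  r <- .forward_net(params, config, list(vox), training = training)
  structure(list(main_prob = r$probs[[1L]], aux_probs = lapply(r$aux_probs, `[[`, 1L)),
            class = "ocunet_outputs")
}
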