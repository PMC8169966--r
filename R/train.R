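#' Step-wise learning-rate schedule
#'
#' `lr = lr0 * factor^(-floor(epoch / period))`: piecewise-constant and
#' non-increasing. Defaults follow the training schedule the network was
#' introduced with: initial rate 0.1, divided by 10 every 1,000 epochs.
#'
#' @param epoch Zero-based epoch index (vectorized).
#' @param lr0 Initial learning rate, or an optimizer config list with
#'   fields `lr`, `decay_factor`, `decay_period`.
#' @param factor Decay divisor (> 1).
#' @param period Epochs between decays (>= 1).
#' @return Learning rate(s).
#' @examples
#' lr_schedule(c(0, 999, 1000, 2500))  # 0.1 0.1 0.01 0.001
#' @export
lr_schedule <- function(epoch, lr0 = 0.1, factor = 10, period = 1000) {
  if (is.list(lr0)) {
    factor <- lr0$decay_factor; period <- lr0$decay_period; lr0 <- lr0$lr
  }
  if (any(epoch < 0)) .stopf("epoch must be >= 0")
  lr0 * factor^(-floor(epoch / period))
}

#' Assemble a full training run configuration
#'
#' Bundles the network architecture, loss weights, optimizer schedule,
#' data source and training loop settings into one validated object; every
#' artifact a run produces embeds this config and the seed.
#'
#' @param network An [ocunet_config()].
#' @param loss List with `weights` (a [loss_weights()]) and `smooth`.
#' @param optimizer List with `lr` (> 0), `decay_factor` (> 1),
#'   `decay_period` (>= 1 epochs) and `momentum`.
#' @param data Either `list(kind = "phantom", n_train =, n_val =, spec =
#'   phantom_spec(...))` or `list(kind = "files", train_dir =, val_dir =,
#'   label = NULL)` with `caseNNNN_img/_seg.nii.gz` pairs.
#' @param training List with `epochs`, `batch_size`, `patch_size`
#'   (`NULL` = whole images), `seed`, `val_every`.
#' @param output List with `dir` (`NULL` = no files written).
#' @return An object of class `run_config`.
#' @export
run_config <- function(network = ocunet_config(),
                       loss = list(weights = loss_weights(), smooth = 1e-5),
                       optimizer = list(lr = 0.1, decay_factor = 10,
                                        decay_period = 1000, momentum = 0.9),
                       data = list(kind = "phantom", n_train = 8, n_val = 4,
                                   spec = phantom_spec()),
                       training = list(epochs = 10, batch_size = 4,
                                       patch_size = NULL, seed = 1, val_every = 10),
                       output = list(dir = NULL)) {
  stopifnot(inherits(network, "ocunet_config"))
  loss <- modifyList(list(weights = loss_weights(
    aux = rep(c(0.5, 0.25), length.out = network$aux_branches)), smooth = 1e-5), loss)
  optimizer <- modifyList(list(lr = 0.1, decay_factor = 10, decay_period = 1000,
                               momentum = 0.9), optimizer)
  training <- modifyList(list(epochs = 10, batch_size = 4, patch_size = NULL,
                              seed = 1, val_every = 10), training)
  if (optimizer$lr <= 0) .stopf("initial learning rate must be > 0")
  if (optimizer$decay_factor <= 1) .stopf("decay factor must be > 1")
  if (optimizer$decay_period < 1) .stopf("decay period must be >= 1")
  if (is.null(training$seed)) .stopf("a seed is required; every artifact records it")
  if (length(loss$weights$aux) != network$aux_branches)
    .stopf("loss has %d aux weights but the network has %d aux branches",
           length(loss$weights$aux), network$aux_branches)
  structure(list(network = network, loss = loss, optimizer = optimizer,
                 data = data, training = training, output = output),
            class = "run_config")
}

# ---- SGD with momentum ---------------------------------------------------

.upd_kernel <- function(kern, g, vel, lr, mom) {
  for (nm in names(kern$weights)) {
    if (is.null(kern$weights[[nm]])) next
    vel$w[[nm]] <- mom * vel$w[[nm]] - lr * g$weights[[nm]]
    kern$weights[[nm]] <- kern$weights[[nm]] + vel$w[[nm]]
  }
  for (nm in c("high", "low")) {
    if (is.null(kern$bias[[nm]]) || is.null(g$bias[[nm]])) next
    vel$b[[nm]] <- mom * vel$b[[nm]] - lr * g$bias[[nm]]
    kern$bias[[nm]] <- kern$bias[[nm]] + vel$b[[nm]]
  }
  list(kern = kern, vel = vel)
}

.upd_bn <- function(st, g, vel, lr, mom) {
  vel$g <- mom * vel$g - lr * g$dgamma
  vel$b <- mom * vel$b - lr * g$dbeta
  st$gamma <- st$gamma + vel$g
  st$beta <- st$beta + vel$b
  list(st = st, vel = vel)
}

.zero_like_kernel <- function(kern) {
  list(w = lapply(kern$weights, function(w) if (is.null(w)) NULL else array(0, dim(w))),
       b = lapply(kern$bias, function(b) if (is.null(b)) NULL else numeric(length(b))))
}

.zero_like_bn <- function(st) list(g = numeric(length(st$gamma)), b = numeric(length(st$beta)))

.init_velocity <- function(params) {
  conv_v <- function(cl) list(
    kernel = .zero_like_kernel(cl$kernel),
    bn = list(high = if (!is.null(cl$bn$high)) .zero_like_bn(cl$bn$high),
              low = if (!is.null(cl$bn$low)) .zero_like_bn(cl$bn$low)))
  list(enc = lapply(params$enc, function(e) list(convs = lapply(e$convs, conv_v))),
       bott = list(convs = lapply(params$bott$convs, conv_v)),
       dec = lapply(params$dec, function(dd) list(
         tconv = .zero_like_kernel(dd$tconv), convs = lapply(dd$convs, conv_v))),
       head = .zero_like_kernel(params$head),
       aux = lapply(params$aux, .zero_like_kernel))
}

.sgd_step <- function(params, grads, vel, lr, mom) {
  upd_convs <- function(convs, g, v) {
    for (i in seq_along(convs)) {
      r <- .upd_kernel(convs[[i]]$kernel, g[[i]], v[[i]]$kernel, lr, mom)
      convs[[i]]$kernel <- r$kern; v[[i]]$kernel <- r$vel
      for (br in c("high", "low")) {
        if (is.null(convs[[i]]$bn[[br]]) || is.null(g[[i]]$bn[[br]])) next
        r <- .upd_bn(convs[[i]]$bn[[br]], g[[i]]$bn[[br]], v[[i]]$bn[[br]], lr, mom)
        convs[[i]]$bn[[br]] <- r$st; v[[i]]$bn[[br]] <- r$vel
      }
    }
    list(convs = convs, v = v)
  }
  for (l in seq_along(params$enc)) {
    r <- upd_convs(params$enc[[l]]$convs, grads$enc[[l]]$convs, vel$enc[[l]]$convs)
    params$enc[[l]]$convs <- r$convs; vel$enc[[l]]$convs <- r$v
  }
  r <- upd_convs(params$bott$convs, grads$bott$convs, vel$bott$convs)
  params$bott$convs <- r$convs; vel$bott$convs <- r$v
  for (l in seq_along(params$dec)) {
    rt <- .upd_kernel(params$dec[[l]]$tconv, grads$dec[[l]]$tconv, vel$dec[[l]]$tconv, lr, mom)
    params$dec[[l]]$tconv <- rt$kern; vel$dec[[l]]$tconv <- rt$vel
    r <- upd_convs(params$dec[[l]]$convs, grads$dec[[l]]$convs, vel$dec[[l]]$convs)
    params$dec[[l]]$convs <- r$convs; vel$dec[[l]]$convs <- r$v
  }
  rh <- .upd_kernel(params$head, grads$head, vel$head, lr, mom)
  params$head <- rh$kern; vel$head <- rh$vel
  for (j in seq_along(params$aux)) {
    ra <- .upd_kernel(params$aux[[j]], grads$aux[[j]], vel$aux[[j]], lr, mom)
    params$aux[[j]] <- ra$kern; vel$aux[[j]] <- ra$vel
  }
  list(params = params, vel = vel)
}

# ---- loss + gradients for one mini-batch ---------------------------------

.put_channel <- function(sp, nc, ch, values) {
  M <- matrix(0, nc, prod(sp))
  M[ch, ] <- values
  array(M, c(nc, sp))
}

.batch_loss_grads <- function(params, config, xs, ys, weights, smooth) {
  fwd <- .forward_net(params, config, xs, training = TRUE, keep_cache = TRUE)
  n <- length(xs)
  nc <- config$num_classes
  total <- 0
  d_main <- vector("list", n)
  d_aux <- lapply(seq_len(config$aux_branches), function(j) vector("list", n))
  for (s in seq_len(n)) {
    sp <- .spatial_dims(fwd$probs[[s]])
    p_fg <- .take_channel(fwd$probs[[s]], nc)
    total <- total + weights$main * soft_dice_loss(p_fg, ys[[s]], smooth)
    g <- .soft_dice_grad(p_fg, ys[[s]], smooth) * (weights$main / n)
    d_main[[s]] <- .put_channel(sp, nc, nc, g)
    for (j in seq_len(config$aux_branches)) {
      a_fg <- .take_channel(fwd$aux_probs[[j]][[s]], nc)
      total <- total + weights$aux[j] * soft_dice_loss(a_fg, ys[[s]], smooth)
      ga <- .soft_dice_grad(a_fg, ys[[s]], smooth) * (weights$aux[j] / n)
      d_aux[[j]][[s]] <- .put_channel(sp, nc, nc, ga)
    }
  }
  grads <- .backward_net(fwd$params, config, fwd$cache, d_main, d_aux)
  list(loss = total / n, grads = grads, params = fwd$params)
}

# ---- data resolution -----------------------------------------------------

.load_case_dir <- function(dir, label = NULL) {
  imgs <- sort(list.files(dir, pattern = "_img\\.nii(\\.gz)?$", full.names = TRUE))
  if (length(imgs) == 0L) .stopf("no caseNNNN_img.nii(.gz) files found in %s", dir)
  lapply(imgs, function(f) {
    seg <- sub("_img\\.nii", "_seg.nii", f)
    if (!file.exists(seg)) .stopf("missing mask for %s", f)
    list(volume = read_volume(f), mask = read_mask(seg, label = label),
         case = sub("_img\\.nii(\\.gz)?$", "", basename(f)))
  })
}

.resolve_training_data <- function(cfg) {
  data <- cfg$data
  seed <- cfg$training$seed
  if (identical(data$kind, "phantom")) {
    gen <- function(i) {
      sp <- data$spec; sp$seed <- (seed %% 100000L) * 10000L + i
      ph <- generate_phantom(sp)
      list(volume = ph$volume, mask = ph$mask, case = sprintf("case%04d", i))
    }
    list(train = lapply(seq_len(data$n_train), gen),
         val = lapply(data$n_train + seq_len(data$n_val), gen))
  } else if (identical(data$kind, "files")) {
    list(train = .load_case_dir(data$train_dir, data$label),
         val = if (!is.null(data$val_dir)) .load_case_dir(data$val_dir, data$label) else list())
  } else .stopf("unknown data kind: %s", data$kind)
}

# pad each case to a network-legal grid; returns arrays
.prep_cases <- function(cases, levels) {
  lapply(cases, function(cs) {
    p <- pad_to_legal(cs$volume, cs$mask, levels)
    x <- p$volume$voxels; dim(x) <- c(1L, dim(x))
    list(x = x, y = p$mask$voxels, crop = p$crop, case = cs$case)
  })
}

#' Train an OCunet
#'
#' Runs mini-batch gradient descent with momentum on the deeply supervised
#' soft Dice objective, following the step-wise learning-rate schedule.
#' Logs per-epoch loss and learning rate, evaluates held-out Dice every
#' `val_every` epochs, and keeps the best-by-validation-Dice parameters
#' alongside the final ones. Fully reproducible given the config seed.
#' Writes `last.rds` / `best.rds` checkpoints (version tag, config and
#' seed embedded) plus a `training_log.csv` when an output directory is
#' configured.
#'
#' @param config A [run_config()].
#' @param verbose Print per-epoch progress?
#' @return An object of class `ocunet_fit` with fields `params`,
#'   `best_params`, `best_val_dice`, `best_epoch`, `config`, `log`
#'   (tibble: epoch, loss, lr, val_dice), `seed`.
#' @export
train_ocunet <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  net <- config$network
  set.seed(config$training$seed)
  dat <- .resolve_training_data(config)
  train <- .prep_cases(dat$train, net$levels)
  val <- .prep_cases(dat$val, net$levels)
  if (length(train) == 0L) .stopf("no training cases")

  params <- ocunet_init(net, input_channels = 1L)
  vel <- .init_velocity(params)
  weights <- config$loss$weights
  smooth <- config$loss$smooth
  epochs <- config$training$epochs
  bs <- max(1L, config$training$batch_size)
  ps <- config$training$patch_size

  best_params <- NULL; best_dice <- -Inf; best_epoch <- NA_integer_
  log_rows <- vector("list", epochs)

  val_dice <- function(p) {
    if (length(val) == 0L) return(NA_real_)
    mean(vapply(val, function(cs) {
      out <- .forward_net(p, net, list(cs$x), training = FALSE)
      prob <- .take_channel(out$probs[[1L]], net$num_classes)
      compute_metrics(prob >= 0.5, cs$y)$dice
    }, numeric(1)))
  }

  for (epoch in seq_len(epochs)) {
    lr <- lr_schedule(epoch - 1L, config$optimizer)
    ord <- sample.int(length(train))
    epoch_loss <- 0; n_seen <- 0L
    for (b0 in seq(1L, length(ord), by = bs)) {
      sel <- ord[b0:min(b0 + bs - 1L, length(ord))]
      if (is.null(ps)) {
        xs <- lapply(train[sel], `[[`, "x")
        ys <- lapply(train[sel], `[[`, "y")
      } else {
        patches <- lapply(train[sel], function(cs) {
          pr <- extract_patches(array(cs$x, dim(cs$x)[-1L]), cs$y, ps,
                                n_patches = 1L, fg_fraction = 1)[[1L]]
          x <- pr$volume; dim(x) <- c(1L, dim(x))
          list(x = x, y = pr$mask)
        })
        xs <- lapply(patches, `[[`, "x")
        ys <- lapply(patches, `[[`, "y")
      }
      r <- .batch_loss_grads(params, net, xs, ys, weights, smooth)
      if (!is.finite(r$loss))
        .stopf("non-finite loss at epoch %d (lr = %g); aborting", epoch, lr)
      params <- r$params  # carries updated batch-norm running stats
      su <- .sgd_step(params, r$grads, vel, lr, config$optimizer$momentum)
      params <- su$params; vel <- su$vel
      epoch_loss <- epoch_loss + r$loss * length(sel)
      n_seen <- n_seen + length(sel)
    }
    epoch_loss <- epoch_loss / n_seen
    vd <- NA_real_
    if (epoch %% config$training$val_every == 0L || epoch == epochs) {
      vd <- val_dice(params)
      if (!is.na(vd) && vd > best_dice) {
        best_dice <- vd; best_params <- params; best_epoch <- epoch
      }
    }
    log_rows[[epoch]] <- tibble::tibble(epoch = epoch, loss = epoch_loss,
                                        lr = lr, val_dice = vd)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  lr %.4g  val_dice %s",
                      epoch, epoch_loss, lr,
                      if (is.na(vd)) "-" else sprintf("%.3f", vd)))
  }

  fit <- structure(list(params = params, best_params = best_params,
                        best_val_dice = if (is.finite(best_dice)) best_dice else NA_real_,
                        best_epoch = best_epoch, config = config,
                        log = do.call(rbind, log_rows),
                        seed = config$training$seed),
                   class = "ocunet_fit")
  out_dir <- config$output$dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    save_checkpoint(fit, file.path(out_dir, "last.rds"), which = "last")
    if (!is.null(best_params))
      save_checkpoint(fit, file.path(out_dir, "best.rds"), which = "best")
    utils::write.csv(fit$log, file.path(out_dir, "training_log.csv"), row.names = FALSE)
  }
  fit
}

#' @export
print.ocunet_fit <- function(x, ...) {
  cat(sprintf("<ocunet_fit> %d epochs, final loss %.4f, best val Dice %s (epoch %s), seed %d\n",
              nrow(x$log), tail(x$log$loss, 1),
              if (is.na(x$best_val_dice)) "-" else sprintf("%.3f", x$best_val_dice),
              if (is.na(x$best_epoch)) "-" else x$best_epoch, x$seed))
  invisible(x)
}

#' Save / load a parameter checkpoint
#'
#' A checkpoint is a single serialized archive with a format version tag,
#' the full run config (network config embedded) and the seed, so any
#' prediction is reproducible from the file alone.
#'
#' @param fit An [train_ocunet()] fit.
#' @param path Destination `.rds` path.
#' @param which `"last"` (final parameters) or `"best"` (best validation
#'   Dice).
#' @return `path` (save) or an `ocunet_checkpoint` list (load).
#' @export
save_checkpoint <- function(fit, path, which = c("last", "best")) {
  which <- match.arg(which)
  p <- if (which == "best") fit$best_params else fit$params
  if (is.null(p)) .stopf("fit has no %s parameters", which)
  saveRDS(structure(list(format_version = 1L, config = fit$config,
                         params = p, seed = fit$seed),
                    class = "ocunet_checkpoint"), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) .stopf("no such checkpoint: %s", path)
  ck <- tryCatch(readRDS(path),
                 error = function(e) .stopf("%s is not an OCunet checkpoint", path))
  if (!inherits(ck, "ocunet_checkpoint") || is.null(ck$format_version))
    .stopf("%s is not an OCunet checkpoint", path)
  ck
}
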