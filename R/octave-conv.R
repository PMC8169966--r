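# thin wrappers over the C++ kernels, operating on (c, spatial...) arrays
.conv_same <- function(x, w, bias = NULL) {
  d <- .ndim_spatial(x)
  .drop_c4(cpp_conv_same(.as_c4(x), .as_k5(w),
                         if (is.null(bias)) numeric(0) else bias), d)
}

.conv_same_bwd_input <- function(dy, w) {
  d <- .ndim_spatial(dy)
  .drop_c4(cpp_conv_same_bwd_input(.as_c4(dy), .as_k5(w)), d)
}

.conv_same_bwd_weight <- function(x, dy, kdim) {
  d <- .ndim_spatial(x)
  k5 <- c(kdim, rep(1L, 3L - length(kdim)))
  dw <- cpp_conv_same_bwd_weight(.as_c4(x), .as_c4(dy), as.integer(k5))
  dim(dw) <- c(dim(dw)[1:2], kdim)
  dw
}

.tconv2 <- function(x, w, bias = NULL) {
  d <- .ndim_spatial(x)
  .drop_c4(cpp_tconv2(.as_c4(x), .as_k5(w),
                      if (is.null(bias)) numeric(0) else bias, d), d)
}

.tconv2_bwd_input <- function(dy, w) {
  d <- .ndim_spatial(dy)
  .drop_c4(cpp_tconv2_bwd_input(.as_c4(dy), .as_k5(w), d), d)
}

.tconv2_bwd_weight <- function(x, dy) {
  d <- .ndim_spatial(x)
  dw <- cpp_tconv2_bwd_weight(.as_c4(x), .as_c4(dy), d)
  dim(dw) <- c(dim(dw)[1:2], rep(2L, d))
  dw
}

.check_oct_input <- function(input, kernel) {
  if (!inherits(input, "multifreq_tensor")) .stopf("input must be a multifreq_tensor")
  if (!inherits(kernel, "octave_kernel")) .stopf("kernel must be an octave_kernel")
  c_h <- if (is.null(input$high)) 0L else dim(input$high)[1L]
  c_l <- if (is.null(input$low)) 0L else dim(input$low)[1L]
  if (c_h != kernel$split_in[["high"]] || c_l != kernel$split_in[["low"]])
    .stopf("input channels (%d high, %d low) do not match kernel alpha_in = %g over c_in = %d",
           c_h, c_l, kernel$alpha_in, kernel$c_in)
  has_low <- kernel$alpha_in > 0 || kernel$alpha_out > 0
  if (has_low && !is.null(input$high) && any(.spatial_dims(input$high) %% 2 != 0))
    .stopf("high-branch spatial dims must be even when any low branch exists")
  if (!is.null(input$high) && .ndim_spatial(input$high) != kernel$d)
    .stopf("input is %d-D but kernel is %d-D", .ndim_spatial(input$high), kernel$d)
  invisible(TRUE)
}

#' Octave convolution forward pass
#'
#' Computes the multifrequency feature transform
#' `Y_H = f_HH(X_H) + f_LH(X_L)` and `Y_L = f_LL(X_L) + f_HL(X_H)`:
#' intra-frequency updates are plain stride-1 "same" convolutions at each
#' branch's own resolution; the low-to-high exchange convolves at low
#' resolution and upsamples by nearest interpolation (scale 2); the
#' high-to-low exchange average-pools (scale 2) and then convolves. Absent
#' branches contribute zero and are omitted.
#'
#' @param input A [multifreq_tensor()] whose channel split matches
#'   `kernel$alpha_in`.
#' @param kernel An [octave_kernel()] (stride-1, odd extent).
#' @return A [multifreq_tensor()] with channel split `kernel$alpha_out`.
#' @seealso [oracle_octave_conv()] for the naive-composition reference.
#' @export
octave_conv_forward <- function(input, kernel) {
  if (kernel$transpose) .stopf("kernel is marked transpose; use octave_transpose_conv_forward()")
  .check_oct_input(input, kernel)
  d <- kernel$d
  w <- kernel$weights
  x_h <- input$high; x_l <- input$low

  y_h <- NULL
  if (kernel$split_out[["high"]] > 0L) {
    if (!is.null(w$hh)) y_h <- .conv_same(x_h, w$hh, kernel$bias$high)
    if (!is.null(w$lh)) {
      lh <- upsample_nearest2(.conv_same(x_l, w$lh, if (is.null(y_h)) kernel$bias$high else NULL))
      y_h <- if (is.null(y_h)) lh else y_h + lh
    }
  }
  y_l <- NULL
  if (kernel$split_out[["low"]] > 0L) {
    if (!is.null(w$ll)) y_l <- .conv_same(x_l, w$ll, kernel$bias$low)
    if (!is.null(w$hl)) {
      hl <- .conv_same(downsample_avg2(x_h), w$hl, if (is.null(y_l)) kernel$bias$low else NULL)
      y_l <- if (is.null(y_l)) hl else y_l + hl
    }
  }
  multifreq_tensor(y_h, y_l, alpha = kernel$alpha_out)
}

#' Naive-composition reference for the octave convolution
#'
#' Computes the same map as [octave_conv_forward()] by literally composing
#' four standard convolutions with explicit average-pooling and
#' nearest-upsampling calls, using pure-R shift-and-add convolution
#' primitives that share no code with the optimized path. Intended as the
#' ground-truth oracle in tests.
#'
#' @inheritParams octave_conv_forward
#' @return A [multifreq_tensor()].
#' @export
oracle_octave_conv <- function(input, kernel) {
  if (kernel$transpose) .stopf("kernel is marked transpose; use oracle_octave_transpose_conv()")
  .check_oct_input(input, kernel)
  w <- kernel$weights
  y_h <- NULL
  if (kernel$split_out[["high"]] > 0L) {
    if (!is.null(w$hh)) y_h <- .r_conv_same(input$high, w$hh, kernel$bias$high)
    if (!is.null(w$lh)) {
      lh <- .r_upsample_nearest2(.r_conv_same(input$low, w$lh,
                                              if (is.null(y_h)) kernel$bias$high else NULL))
      y_h <- if (is.null(y_h)) lh else y_h + lh
    }
  }
  y_l <- NULL
  if (kernel$split_out[["low"]] > 0L) {
    if (!is.null(w$ll)) y_l <- .r_conv_same(input$low, w$ll, kernel$bias$low)
    if (!is.null(w$hl)) {
      hl <- .r_conv_same(.r_avgpool2(input$high), w$hl,
                         if (is.null(y_l)) kernel$bias$low else NULL)
      y_l <- if (is.null(y_l)) hl else y_l + hl
    }
  }
  multifreq_tensor(y_h, y_l, alpha = kernel$alpha_out)
}

#' Octave transpose convolution (stride 2) forward pass
#'
#' The decoder's learnable upsampling operator: each of the four frequency
#' paths applies a stride-2 transpose convolution (extent-2,
#' non-overlapping) at its branch's resolution, and inter-frequency
#' exchange reuses the same average-pool / nearest-upsample primitives as
#' the forward operator. Every output spatial dimension is exactly twice
#' its input counterpart, per branch.
#'
#' @param input A [multifreq_tensor()] matching `kernel$alpha_in`.
#' @param kernel An [octave_kernel()] created with `transpose = TRUE`.
#' @return A [multifreq_tensor()] with doubled spatial dims.
#' @export
octave_transpose_conv_forward <- function(input, kernel) {
  if (!kernel$transpose) .stopf("kernel is not marked transpose")
  .check_oct_input(input, kernel)
  w <- kernel$weights
  y_h <- NULL
  if (kernel$split_out[["high"]] > 0L) {
    if (!is.null(w$hh)) y_h <- .tconv2(input$high, w$hh, kernel$bias$high)
    if (!is.null(w$lh)) {
      lh <- upsample_nearest2(.tconv2(input$low, w$lh,
                                      if (is.null(y_h)) kernel$bias$high else NULL))
      y_h <- if (is.null(y_h)) lh else y_h + lh
    }
  }
  y_l <- NULL
  if (kernel$split_out[["low"]] > 0L) {
    if (!is.null(w$ll)) y_l <- .tconv2(input$low, w$ll, kernel$bias$low)
    if (!is.null(w$hl)) {
      hl <- .tconv2(downsample_avg2(input$high), w$hl,
                    if (is.null(y_l)) kernel$bias$low else NULL)
      y_l <- if (is.null(y_l)) hl else y_l + hl
    }
  }
  multifreq_tensor(y_h, y_l, alpha = kernel$alpha_out)
}

#' Naive-composition reference for the octave transpose convolution
#'
#' Pure-R scatter-based transpose convolutions plus explicit resampling,
#' mirroring [oracle_octave_conv()]. Test oracle only.
#'
#' @inheritParams octave_transpose_conv_forward
#' @return A [multifreq_tensor()].
#' @export
oracle_octave_transpose_conv <- function(input, kernel) {
  if (!kernel$transpose) .stopf("kernel is not marked transpose")
  .check_oct_input(input, kernel)
  w <- kernel$weights
  y_h <- NULL
  if (kernel$split_out[["high"]] > 0L) {
    if (!is.null(w$hh)) y_h <- .r_tconv2(input$high, w$hh, kernel$bias$high)
    if (!is.null(w$lh)) {
      lh <- .r_upsample_nearest2(.r_tconv2(input$low, w$lh,
                                           if (is.null(y_h)) kernel$bias$high else NULL))
      y_h <- if (is.null(y_h)) lh else y_h + lh
    }
  }
  y_l <- NULL
  if (kernel$split_out[["low"]] > 0L) {
    if (!is.null(w$ll)) y_l <- .r_tconv2(input$low, w$ll, kernel$bias$low)
    if (!is.null(w$hl)) {
      hl <- .r_tconv2(.r_avgpool2(input$high), w$hl,
                      if (is.null(y_l)) kernel$bias$low else NULL)
      y_l <- if (is.null(y_l)) hl else y_l + hl
    }
  }
  multifreq_tensor(y_h, y_l, alpha = kernel$alpha_out)
}

# --- adjoints of the two operators, used by the training loop -------------

# returns list(d_input = multifreq-like list, d_weights, d_bias)
.octave_conv_backward <- function(input, kernel, d_out) {
  d <- kernel$d
  w <- kernel$weights
  dy_h <- d_out$high; dy_l <- d_out$low
  dx_h <- dx_l <- NULL
  dw <- list(hh = NULL, lh = NULL, ll = NULL, hl = NULL)
  kdim <- rep(kernel$k, d)

  if (!is.null(w$hh) && !is.null(dy_h)) {
    dx_h <- .conv_same_bwd_input(dy_h, w$hh)
    dw$hh <- .conv_same_bwd_weight(input$high, dy_h, kdim)
  }
  if (!is.null(w$lh) && !is.null(dy_h)) {
    g <- .upsample2_adj(dy_h, d)
    dl <- .conv_same_bwd_input(g, w$lh)
    dx_l <- if (is.null(dx_l)) dl else dx_l + dl
    dw$lh <- .conv_same_bwd_weight(input$low, g, kdim)
  }
  if (!is.null(w$ll) && !is.null(dy_l)) {
    dl <- .conv_same_bwd_input(dy_l, w$ll)
    dx_l <- if (is.null(dx_l)) dl else dx_l + dl
    dw$ll <- .conv_same_bwd_weight(input$low, dy_l, kdim)
  }
  if (!is.null(w$hl) && !is.null(dy_l)) {
    x_avg <- downsample_avg2(input$high)
    dh <- .avgpool2_adj(.conv_same_bwd_input(dy_l, w$hl), d)
    dx_h <- if (is.null(dx_h)) dh else dx_h + dh
    dw$hl <- .conv_same_bwd_weight(x_avg, dy_l, kdim)
  }
  db <- list(
    high = if (!is.null(kernel$bias$high) && !is.null(dy_h)) cpp_channel_sums(.as_c4(dy_h)),
    low = if (!is.null(kernel$bias$low) && !is.null(dy_l)) cpp_channel_sums(.as_c4(dy_l))
  )
  list(d_input = list(high = dx_h, low = dx_l), d_weights = dw, d_bias = db)
}

.octave_tconv_backward <- function(input, kernel, d_out) {
  d <- kernel$d
  w <- kernel$weights
  dy_h <- d_out$high; dy_l <- d_out$low
  dx_h <- dx_l <- NULL
  dw <- list(hh = NULL, lh = NULL, ll = NULL, hl = NULL)

  if (!is.null(w$hh) && !is.null(dy_h)) {
    dx_h <- .tconv2_bwd_input(dy_h, w$hh)
    dw$hh <- .tconv2_bwd_weight(input$high, dy_h)
  }
  if (!is.null(w$lh) && !is.null(dy_h)) {
    g <- .upsample2_adj(dy_h, d)
    dl <- .tconv2_bwd_input(g, w$lh)
    dx_l <- if (is.null(dx_l)) dl else dx_l + dl
    dw$lh <- .tconv2_bwd_weight(input$low, g)
  }
  if (!is.null(w$ll) && !is.null(dy_l)) {
    dl <- .tconv2_bwd_input(dy_l, w$ll)
    dx_l <- if (is.null(dx_l)) dl else dx_l + dl
    dw$ll <- .tconv2_bwd_weight(input$low, dy_l)
  }
  if (!is.null(w$hl) && !is.null(dy_l)) {
    x_avg <- downsample_avg2(input$high)
    dh <- .avgpool2_adj(.tconv2_bwd_input(dy_l, w$hl), d)
    dx_h <- if (is.null(dx_h)) dh else dx_h + dh
    dw$hl <- .tconv2_bwd_weight(x_avg, dy_l)
  }
  db <- list(
    high = if (!is.null(kernel$bias$high) && !is.null(dy_h)) cpp_channel_sums(.as_c4(dy_h)),
    low = if (!is.null(kernel$bias$low) && !is.null(dy_l)) cpp_channel_sums(.as_c4(dy_l))
  )
  list(d_input = list(high = dx_h, low = dx_l), d_weights = dw, d_bias = db)
}
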