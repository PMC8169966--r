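#' Construct a partitioned octave-convolution kernel
#'
#' The kernel of an octave convolution is partitioned into four blocks
#' `W = [W_HH, W_LH, W_LL, W_HL]` that update each frequency branch from
#' itself (intra-frequency) and from the other branch (inter-frequency
#' exchange). The four blocks together hold exactly `k^d * c_in * c_out`
#' weights for every choice of `alpha` — the partition re-arranges a vanilla
#' kernel without adding or removing parameters. Blocks touching an absent
#' branch are `NULL`.
#'
#' @param k Kernel extent per spatial dimension. Odd for the stride-1
#'   operator; transpose kernels (`transpose = TRUE`) use `k = 2` with
#'   stride 2.
#' @param c_in,c_out Total input/output channel counts.
#' @param alpha_in,alpha_out Low-frequency channel fraction on the input and
#'   output side.
#' @param d Spatial dimensionality, 2 or 3.
#' @param bias Include per-output-channel biases?
#' @param init `"gaussian"` (zero-mean, `init_sd`) or `"zeros"`. Gaussian
#'   initialization draws from the current RNG stream, so it is seedable
#'   with [set.seed()].
#' @param init_sd Standard deviation of the Gaussian initializer.
#' @param transpose Mark this kernel for the stride-2 transpose operator.
#' @return An object of class `octave_kernel`.
#' @examples
#' kern <- octave_kernel(3, c_in = 4, c_out = 8, alpha_in = 0.5, alpha_out = 0.5)
#' param_count(kern)  # 9 * 4 * 8 = 288, independent of alpha
#' @export
octave_kernel <- function(k, c_in, c_out, alpha_in = 0.5, alpha_out = 0.5,
                          d = 2, bias = TRUE, init = c("gaussian", "zeros"),
                          init_sd = 0.01, transpose = FALSE) {
  init <- match.arg(init)
  if (!d %in% c(2L, 3L)) .stopf("d must be 2 or 3")
  if (!.is_count(k) || k < 1) .stopf("k must be a positive integer")
  if (transpose) {
    if (k != 2) .stopf("transpose kernels use extent 2 (stride 2)")
  } else if (k %% 2 == 0) .stopf("stride-1 kernel extent must be odd")
  s_in <- split_channels(c_in, alpha_in)
  s_out <- split_channels(c_out, alpha_out)

  make_block <- function(co, ci) {
    if (co == 0L || ci == 0L) return(NULL)
    n <- co * ci * k^d
    v <- if (init == "gaussian") rnorm(n, sd = init_sd) else numeric(n)
    array(v, c(co, ci, rep(k, d)))
  }
  weights <- list(
    hh = make_block(s_out[["high"]], s_in[["high"]]),
    lh = make_block(s_out[["high"]], s_in[["low"]]),
    ll = make_block(s_out[["low"]], s_in[["low"]]),
    hl = make_block(s_out[["low"]], s_in[["high"]])
  )
  biases <- if (bias) {
    list(high = if (s_out[["high"]] > 0L) numeric(s_out[["high"]]),
         low = if (s_out[["low"]] > 0L) numeric(s_out[["low"]]))
  } else list(high = NULL, low = NULL)

  structure(list(k = as.integer(k), d = as.integer(d),
                 c_in = as.integer(c_in), c_out = as.integer(c_out),
                 alpha_in = alpha_in, alpha_out = alpha_out,
                 split_in = s_in, split_out = s_out,
                 weights = weights, bias = biases,
                 transpose = isTRUE(transpose)),
            class = "octave_kernel")
}

#' @export
print.octave_kernel <- function(x, ...) {
  cat(sprintf("<octave_kernel>%s k=%d d=%d  %d -> %d channels  alpha %g -> %g  (%d weights)\n",
              if (x$transpose) " transpose(stride 2)" else "",
              x$k, x$d, x$c_in, x$c_out, x$alpha_in, x$alpha_out,
              param_count(x)))
  invisible(x)
}

#' Parameter count of an octave kernel
#'
#' Sums the element counts of the four weight blocks (plus `c_out` when
#' biases are included). Without biases the total equals
#' `k^d * c_in * c_out` for every `alpha`: partitioning the kernel across
#' frequencies conserves parameters exactly.
#'
#' @param kernel An [octave_kernel()].
#' @param include_bias Count bias terms too?
#' @return Integer parameter count.
#' @export
param_count <- function(kernel, include_bias = FALSE) {
  stopifnot(inherits(kernel, "octave_kernel"))
  n <- sum(vapply(kernel$weights, function(w) if (is.null(w)) 0L else length(w), integer(1)))
  if (include_bias)
    n <- n + sum(vapply(kernel$bias, function(b) if (is.null(b)) 0L else length(b), integer(1)))
  n
}

#' Multiply-accumulate count of one octave convolution
#'
#' Analytic count of multiply–accumulate operations for a stride-1 "same"
#' octave convolution applied to a high branch of the given spatial size:
#' each of the four paths contributes (output cells at that path's working
#' resolution) x `k^d` x (input channels of the path). The three paths that
#' involve the low branch run at half resolution, so the count decreases
#' monotonically in `alpha`; at `alpha = 0` it equals the vanilla count
#' `k^d * c_in * c_out * prod(spatial)`.
#'
#' @param kernel An [octave_kernel()].
#' @param high_spatial Spatial dims of the high-frequency input branch
#'   (even whenever a low branch exists).
#' @return Number of multiply–accumulates (double, as counts can be large).
#' @export
flop_count <- function(kernel, high_spatial) {
  stopifnot(inherits(kernel, "octave_kernel"))
  if (length(high_spatial) != kernel$d) .stopf("high_spatial must have %d dims", kernel$d)
  has_low <- kernel$split_in[["low"]] > 0L || kernel$split_out[["low"]] > 0L
  if (has_low && any(high_spatial %% 2 != 0)) .stopf("spatial dims must be even when a low branch exists")
  s_high <- prod(high_spatial)
  s_low <- s_high / 2^kernel$d
  kvol <- kernel$k^kernel$d
  ci_h <- kernel$split_in[["high"]]; ci_l <- kernel$split_in[["low"]]
  co_h <- kernel$split_out[["high"]]; co_l <- kernel$split_out[["low"]]
  # H->H at high res; L->H, L->L, H->L all at low res
  kvol * (s_high * ci_h * co_h + s_low * ci_l * co_h +
            s_low * ci_l * co_l + s_low * ci_h * co_l)
}
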