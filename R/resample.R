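#' Average-pool a feature map by a factor of two
#'
#' Each output cell is the arithmetic mean of its `2^d` input block, so the
#' global sum is preserved up to the factor `2^d`. This is the
#' down-sampling primitive of the octave operator's high-to-low path.
#'
#' @param x Channel-first array `(c, s1, ..., sd)` with every spatial
#'   dimension even.
#' @return Array `(c, s1/2, ..., sd/2)`.
#' @export
downsample_avg2 <- function(x) {
  d <- .ndim_spatial(x)
  sp <- .spatial_dims(x)
  if (any(sp %% 2 != 0))
    .stopf("all spatial dimensions must be even, got (%s); pad first",
           paste(sp, collapse = "x"))
  .drop_c4(cpp_avgpool2(.as_c4(x), d), d)
}

#' Nearest-neighbour upsample a feature map by a factor of two
#'
#' `out[p] = in[floor(p/2)]` along every spatial axis (each input cell is
#' replicated into a `2^d` block), the up-sampling primitive of the octave
#' operator's low-to-high path. Exact left inverse of [downsample_avg2()]:
#' `downsample_avg2(upsample_nearest2(x))` recovers `x`.
#'
#' @param x Channel-first array `(c, s1, ..., sd)`.
#' @return Array `(c, 2*s1, ..., 2*sd)`.
#' @export
upsample_nearest2 <- function(x) {
  d <- .ndim_spatial(x)
  .drop_c4(cpp_upsample_nearest2(.as_c4(x), d), d)
}

# adjoint of downsample_avg2: spread each gradient cell over its 2^d block / 2^d
.avgpool2_adj <- function(g, d) {
  .drop_c4(cpp_upsample_nearest2(.as_c4(g), d), d) / 2^d
}

# adjoint of upsample_nearest2: sum each 2^d block (= 2^d * average)
.upsample2_adj <- function(g, d) {
  .drop_c4(cpp_avgpool2(.as_c4(g), d), d) * 2^d
}
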