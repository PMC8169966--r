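# Internal array helpers. Feature maps are channel-first dense arrays with
# dim (c, s1, ..., sd), d in {2, 3}. The C++ kernels always see 4 dims
# (c, sx, sy, sz); 2-D data is padded with a trailing singleton axis.

.spatial_dims <- function(x) dim(x)[-1L]

.ndim_spatial <- function(x) length(dim(x)) - 1L

.as_c4 <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("expected a (channels, spatial...) array with 2 or 3 spatial dims", call. = FALSE)
  x
}

.drop_c4 <- function(x, d) {
  dims <- dim(x)
  dim(x) <- dims[seq_len(d + 1L)]
  x
}

.as_k5 <- function(w) {
  d <- dim(w)
  if (length(d) == 4L) dim(w) <- c(d, 1L)
  else if (length(d) != 5L) stop("expected a (c_out, c_in, k...) kernel array", call. = FALSE)
  w
}

# index a (channels, spatial...) array by per-axis spatial index vectors
.slab <- function(x, idx) {
  do.call(`[`, c(list(x, TRUE), idx, list(drop = FALSE)))
}

.slab_assign <- function(x, idx, value) {
  do.call(`[<-`, c(list(x, TRUE), idx, list(value = value)))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x)
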