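#' Split a channel budget between the high- and low-frequency branches
#'
#' The low-frequency branch receives `round(alpha * c_total)` channels
#' (round-half-to-even, as in base [round()]) and the high-frequency branch
#' the remainder, so the two branches always sum to `c_total`.
#'
#' @param c_total Total number of channels (positive integer).
#' @param alpha Fraction of channels assigned to the low-frequency branch,
#'   in `[0, 1]`. `alpha = 0` recovers a vanilla single-frequency layer.
#' @return Named integer vector with elements `high` and `low`.
#' @examples
#' split_channels(16, 0.5)
#' split_channels(16, 0)
#' @export
split_channels <- function(c_total, alpha) {
  if (!.is_count(c_total) || c_total < 1) .stopf("c_total must be a positive integer")
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0 || alpha > 1)
    .stopf("alpha must be a single value in [0, 1]")
  c_low <- as.integer(round(alpha * c_total))
  c(high = as.integer(c_total) - c_low, low = c_low)
}

#' Construct a multifrequency feature tensor
#'
#' A multifrequency tensor pairs a high-frequency feature map with a
#' low-frequency one living one octave below it: every spatial dimension of
#' `low` is exactly half the corresponding dimension of `high`. Either
#' branch may be absent (`alpha = 0` drops `low`, `alpha = 1` drops `high`).
#'
#' @param high Channel-first array `(c_high, s1, ..., sd)`, or `NULL` when
#'   `alpha = 1`.
#' @param low Channel-first array `(c_low, s1/2, ..., sd/2)`, or `NULL` when
#'   `alpha = 0`.
#' @param alpha Fraction of total channels on the low branch. Inferred from
#'   the channel counts when omitted.
#' @return An object of class `multifreq_tensor` with fields `high`, `low`,
#'   `alpha`.
#' @export
multifreq_tensor <- function(high, low = NULL, alpha = NULL) {
  if (is.null(high) && is.null(low)) .stopf("at least one branch must be present")
  c_h <- if (is.null(high)) 0L else dim(high)[1L]
  c_l <- if (is.null(low)) 0L else dim(low)[1L]
  if (is.null(alpha)) alpha <- c_l / (c_h + c_l)
  if (alpha == 0 && !is.null(low)) .stopf("alpha = 0 but a low branch is present")
  if (alpha == 1 && !is.null(high)) .stopf("alpha = 1 but a high branch is present")
  if (alpha > 0 && is.null(low)) .stopf("alpha > 0 but the low branch is absent")
  if (alpha < 1 && is.null(high)) .stopf("alpha < 1 but the high branch is absent")
  split <- split_channels(c_h + c_l, alpha)
  if (split[["high"]] != c_h || split[["low"]] != c_l)
    .stopf("channel counts (%d, %d) inconsistent with alpha = %g", c_h, c_l, alpha)
  if (!is.null(high) && !is.null(low)) {
    sh <- .spatial_dims(high); sl <- .spatial_dims(low)
    if (length(sh) != length(sl)) .stopf("branches differ in spatial dimensionality")
    if (any(sh %% 2L != 0L)) .stopf("high-branch spatial dims must be even when a low branch is present")
    if (any(sl != sh %/% 2L))
      .stopf("low branch must be one octave below high: expected (%s), got (%s)",
             paste(sh %/% 2L, collapse = "x"), paste(sl, collapse = "x"))
  }
  structure(list(high = high, low = low, alpha = alpha), class = "multifreq_tensor")
}

#' @export
print.multifreq_tensor <- function(x, ...) {
  fmt <- function(a) if (is.null(a)) "absent" else paste(dim(a), collapse = " x ")
  cat("<multifreq_tensor> alpha =", x$alpha,
      "\n  high:", fmt(x$high), "\n  low: ", fmt(x$low), "\n")
  invisible(x)
}

# total channel count of a multifrequency tensor
.mf_channels <- function(x) {
  (if (is.null(x$high)) 0L else dim(x$high)[1L]) +
    (if (is.null(x$low)) 0L else dim(x$low)[1L])
}

.mf_spatial <- function(x) {
  if (!is.null(x$high)) .spatial_dims(x$high) else 2L * .spatial_dims(x$low)
}
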