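#' @keywords internal
#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Linear interpolation of a causal signal
#'
#' Interpolates (t, y) at xout, returning 0 for xout < min(t) (tracer absent
#' before arrival) and the last value for xout > max(t).
#' @keywords internal
#' @noRd
interp_causal <- function(t, y, xout) {
  n <- length(t)
  out <- numeric(length(xout))
  idx <- findInterval(xout, t)
  inside <- idx >= 1L & idx < n
  above <- idx >= n
  i <- idx[inside]
  w <- (xout[inside] - t[i]) / (t[i + 1L] - t[i])
  out[inside] <- (1 - w) * y[i] + w * y[i + 1L]
  out[above] <- y[n]
  # below min(t): exact grid hit at t[1] handled by findInterval (idx==1),
  # anything strictly earlier stays 0
  out
}

#' Cumulative trapezoidal integral sampled with zero-padding for negative times
#' @keywords internal
#' @noRd
cumtrapz_vec <- function(t, y) {
  as.numeric(pracma::cumtrapz(t, y))
}

#' Check a scalar is a finite non-negative number
#' @keywords internal
#' @noRd
check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stopf("`%s` must be a single finite non-negative number", name)
  invisible(x)
}
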