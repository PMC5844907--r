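## Separable 2D Savitzky-Golay smoothing.
##
## The 1D pass follows the standard filter semantics: interior points use the
## central least-squares kernel; the first/last half-windows use off-center
## rows of a projection matrix (a polynomial fit to the terminal window
## evaluated at the edge points).  The edge fit is order 1 regardless of the
## interior order: a least-squares line evaluated at the window end is
## stable, whereas a cubic evaluated there has large-variance, large-negative
## weights that ring on residual structure -- and order 1 already reproduces
## the linear illumination ramps the filter must preserve exactly, borders
## included.

sg_smooth_cols <- function(X, window, order) {
  L <- nrow(X)
  if (window >= L) stop("SFS too large for plane")
  k <- (window - 1L) %/% 2L
  Fm <- unclass(signal::sgolay(p = order, n = window))
  Fe <- unclass(signal::sgolay(p = min(order, 1L), n = window))
  Y <- stats::filter(X, Fm[k + 1L, ], method = "convolution", sides = 2)
  Y <- matrix(as.numeric(Y), nrow = L)
  Y[1:k, ] <- Fe[1:k, , drop = FALSE] %*% X[1:window, , drop = FALSE]
  Y[(L - k + 1L):L, ] <- Fe[(k + 2L):window, , drop = FALSE] %*%
    X[(L - window + 1L):L, , drop = FALSE]
  Y
}

#' Separable 2D Savitzky-Golay smoothing
#'
#' Applies a 1D Savitzky-Golay filter along rows then columns. Edge points
#' are handled by order-1 least-squares fits over the terminal windows (see
#' source note), so constants and linear ramps are reproduced exactly over
#' the whole plane, higher-order structure exactly in the interior.
#'
#' @param x numeric matrix.
#' @param window odd filter window (the spatial filter size, SFS), must be
#'   smaller than both matrix dimensions; even values are coerced up to odd.
#' @param order polynomial order (>= 1, window >= order + 2).
#' @return smoothed matrix of the same dimension.
#' @export
sg_smooth_2d <- function(x, window, order = 3) {
  window <- coerce_odd(window)
  if (order < 1) stop("sg order must be >= 1")
  if (window < order + 2) stop("window must be >= order + 2")
  if (window >= min(dim(x))) stop("SFS too large for plane")
  # along rows (x direction), then columns (y direction); linear, so order
  # of the passes does not matter
  t(sg_smooth_cols(t(sg_smooth_cols(x, window, order)), window, order))
}
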