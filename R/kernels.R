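#' Sampled Gaussian (derivative) kernel
#'
#' One-dimensional sampled Gaussian kernel or one of its first two
#' derivatives, truncated at `truncate` standard deviations.  The
#' zeroth-order kernel is normalized to unit sum; derivative kernels are
#' the corresponding Hermite-weighted versions of the normalized Gaussian,
#' so that convolving a polynomial of matching degree reproduces its exact
#' derivative in the kernel interior.
#'
#' @param sigma standard deviation in pixels (> 0).
#' @param order derivative order, 0, 1 or 2.
#' @param truncate kernel half-width in units of `sigma`.
#' @return numeric vector of odd length `2 * ceiling(truncate * sigma) + 1`.
#' @keywords internal
gaussian_kernel_1d <- function(sigma, order = 0, truncate = 3) {
  stopifnot(sigma > 0, order %in% 0:2)
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  x <- seq.int(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
    "0" = g,
    # sign convention: correlation with these taps equals d/dx of the
    # smoothed signal (kernels are symmetric/antisymmetric, so
    # convolution vs correlation only flips the odd-order sign)
    "1" = x / sigma^2 * g,
    "2" = {
      k2 <- (x^2 / sigma^4 - 1 / sigma^2) * g
      # remove the residual DC response of the truncated sampled kernel
      # so that flat images have exactly zero second derivative
      k2 - sum(k2) * g
    }
  )
}

# Separable convolution of a 2D matrix (reflect boundary); k0 along rows
# (y), k1 along columns (x).  NULL skips an axis.
conv_sep2 <- function(img, k0 = NULL, k1 = NULL) {
  .cf_conv_sep2(img,
                if (is.null(k0)) numeric(0) else k0,
                if (is.null(k1)) numeric(0) else k1)
}

# Separable convolution of a 3D array (reflect boundary); kernels is a
# list of three 1D kernels (or NULL) for the array's dims in order.
conv_sep3 <- function(vol, kernels) {
  stopifnot(length(dim(vol)) == 3L, length(kernels) == 3L)
  .cf_conv_sep3(vol, dim(vol), kernels)
}
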