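#' Multiscale 2D filter-bank features
#'
#' Computes, for each channel of a 2D plane and each scale `s`, five
#' features of the Gaussian scale space: the Gaussian-smoothed image, the
#' Gaussian gradient magnitude, the Laplacian of Gaussian, and the minimum
#' and maximum eigenvalues of the 2x2 Hessian (curvature) matrix — plus,
#' optionally, the raw channel itself.  These per-pixel feature vectors are
#' what the proximity regressor is trained on; the same deterministic
#' feature order is used at training and prediction (it is recorded in the
#' saved model and checked on load).
#'
#' Bright round objects give a strongly negative minimum curvature
#' eigenvalue and LoG at the matching scale, which is what lets the
#' regressor tell cell interiors from edges and background.
#'
#' All convolutions use reflect (symmetric) boundary handling.
#'
#' @param plane numeric matrix `(y, x)` or array `(y, x, c)`.
#' @param scales Gaussian scales (sigma, pixels); default `c(1, 2, 4, 8, 16)`.
#' @param include_raw include the raw channel as a feature (default TRUE).
#' @return numeric array `(y, x, f)` with attribute `feature_spec`, a
#'   data.frame of `(filter, scale, channel)` in feature order.
#' @examples
#' fs <- compute_filter_bank(matrix(runif(64 * 64), 64), scales = c(1, 2))
#' dim(fs)[3]  # 2 * 5 + 1 features
#' @export
compute_filter_bank <- function(plane, scales = c(1, 2, 4, 8, 16),
                                include_raw = TRUE) {
  if (is.matrix(plane)) plane <- array(plane, dim = c(dim(plane), 1))
  stopifnot(length(dim(plane)) == 3L)
  if (any(!is.finite(plane))) stop("plane contains non-finite values")
  if (length(scales) == 0 || any(scales <= 0))
    stop("scales must be strictly positive")
  nc <- dim(plane)[3]
  spec <- feature_spec(scales, include_raw, nc)
  out <- array(0, dim = c(dim(plane)[1:2], nrow(spec)))
  f <- 1L
  for (ch in seq_len(nc)) {
    p <- plane[, , ch]
    if (include_raw) {
      out[, , f] <- p
      f <- f + 1L
    }
    for (s in scales) {
      k0 <- gaussian_kernel_1d(s, 0)
      k1 <- gaussian_kernel_1d(s, 1)
      k2 <- gaussian_kernel_1d(s, 2)
      g   <- conv_sep2(p, k0, k0)
      gy  <- conv_sep2(p, k1, k0)
      gx  <- conv_sep2(p, k0, k1)
      gyy <- conv_sep2(p, k2, k0)
      gxx <- conv_sep2(p, k0, k2)
      gxy <- conv_sep2(p, k1, k1)
      tr <- gyy + gxx
      disc <- sqrt(pmax((gyy - gxx)^2 + 4 * gxy^2, 0))
      out[, , f]      <- g
      out[, , f + 1L] <- sqrt(gy^2 + gx^2)
      out[, , f + 2L] <- tr
      out[, , f + 3L] <- (tr - disc) / 2  # min curvature eigenvalue
      out[, , f + 4L] <- (tr + disc) / 2  # max curvature eigenvalue
      f <- f + 5L
    }
  }
  attr(out, "feature_spec") <- spec
  out
}

#' Feature-bank specification
#'
#' Deterministic ordering of the filter-bank features for a given scale
#' set, channel count and raw-intensity flag.
#'
#' @param scales Gaussian scales.
#' @param include_raw whether the raw channel is a feature.
#' @param n_channels channel count.
#' @return data.frame with columns `filter`, `scale`, `channel`.
#' @export
feature_spec <- function(scales, include_raw = TRUE, n_channels = 1L) {
  filters <- c("gaussian", "gradient_magnitude", "laplacian_of_gaussian",
               "curvature_eig_min", "curvature_eig_max")
  rows <- list()
  for (ch in seq_len(n_channels)) {
    if (include_raw)
      rows[[length(rows) + 1L]] <- data.frame(filter = "raw", scale = 0,
                                              channel = ch)
    for (s in scales)
      rows[[length(rows) + 1L]] <- data.frame(filter = filters, scale = s,
                                              channel = ch)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Feature matrix (pixels x features) for an annotated plane, restricted to
# a rectangular region (0-based inclusive bounds), rows in column-major
# (y fastest) order over the region.
features_in_region <- function(fstack, region) {
  ys <- (region[1]:region[3]) + 1L
  xs <- (region[2]:region[4]) + 1L
  nf <- dim(fstack)[3]
  sub <- fstack[ys, xs, , drop = FALSE]
  matrix(sub, nrow = length(ys) * length(xs), ncol = nf)
}
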