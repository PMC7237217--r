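#' Expected object size
#'
#' Radii of the objects to detect, in voxels, in `(z, y, x)` axis order
#' (the package's coordinate convention); `hy = hx` for objects spherical
#' in-plane.  Anisotropic voxel spacing is absorbed by giving `hz` in
#' voxels rather than micrometres.
#'
#' @param h scalar radius or `c(hz, hy, hx)`.
#' @return object of class `object_size` (numeric length 3).
#' @export
object_size <- function(h) {
  h <- as.numeric(h)
  if (length(h) == 1L) h <- rep(h, 3)
  if (length(h) != 3L || any(h <= 0))
    stop("object size must be a positive radius or c(hz, hy, hx)")
  structure(h, class = "object_size")
}

#' Determinant-of-Hessian blob enhancement
#'
#' Smooths the proximity volume with an anisotropic Gaussian at scale
#' `h / 2` per axis (slightly smaller than the object radius, where blob
#' response is near-optimal) and computes the determinant of the 3x3
#' Hessian at every voxel.  For a bright blob all three Hessian
#' eigenvalues are negative, so the determinant is negative there; the
#' returned response is `max(0, -det)`, positive on blobs of the selected
#' size and ~0 on background, ridges and plate-like structure.
#'
#' @param pv a [proximity_volume()] (or plain `(t, z, y, x)` array).
#' @param size an [object_size()] (expected radii, voxels).
#' @return array `(t, z, y, x)` of blob responses, with attribute `size`.
#' @export
hessian_enhance <- function(pv, size) {
  vals <- if (inherits(pv, "proximity_volume")) pv$values else pv
  stopifnot(length(dim(vals)) == 4L)
  size <- object_size(size)
  d <- dim(vals)
  if (any(size >= d[2:4]))
    stop("object size exceeds the volume extent")
  sig <- as.numeric(size) / 2
  k0 <- lapply(sig, gaussian_kernel_1d, order = 0)
  k1 <- lapply(sig, gaussian_kernel_1d, order = 1)
  k2 <- lapply(sig, gaussian_kernel_1d, order = 2)
  out <- array(0, dim = d)
  for (t in seq_len(d[1])) {
    v <- vals[t, , , ]
    dim(v) <- d[2:4]
    dzz <- conv_sep3(v, list(k2[[1]], k0[[2]], k0[[3]]))
    dyy <- conv_sep3(v, list(k0[[1]], k2[[2]], k0[[3]]))
    dxx <- conv_sep3(v, list(k0[[1]], k0[[2]], k2[[3]]))
    dzy <- conv_sep3(v, list(k1[[1]], k1[[2]], k0[[3]]))
    dzx <- conv_sep3(v, list(k1[[1]], k0[[2]], k1[[3]]))
    dyx <- conv_sep3(v, list(k0[[1]], k1[[2]], k1[[3]]))
    det <- dzz * (dyy * dxx - dyx^2) -
           dzy * (dzy * dxx - dyx * dzx) +
           dzx * (dzy * dyx - dyy * dzx)
    out[t, , , ] <- pmax(0, -det)
  }
  attr(out, "size") <- as.numeric(size)
  attr(out, "ts") <- if (inherits(pv, "proximity_volume")) pv$ts
                     else seq_len(d[1]) - 1L
  out
}

#' 3D maxima finding
#'
#' Extracts detections as voxels that are strict maxima of the enhanced
#' response within an ellipsoidal neighbourhood of radii `h`, and whose
#' response exceeds `threshold` times the per-timepoint maximum response
#' (the threshold sets the detection sensitivity and is dimensionless so
#' it transfers across images).  Plateaus of equal value yield one
#' detection at the plateau centroid.  Detections within `h` of the volume
#' border are kept but flagged in the `border` column.
#'
#' @param enhanced output of [hessian_enhance()] (array `(t, z, y, x)`).
#' @param size an [object_size()].
#' @param threshold relative response threshold in `[0, 1)`, default 0.1.
#' @param class_id class label for the resulting detections.
#' @return a [detection_set()]; scores are responses relative to the
#'   per-timepoint maximum, in `(threshold, 1]`.
#' @export
find_maxima <- function(enhanced, size, threshold = 0.1, class_id = "cell") {
  stopifnot(length(dim(enhanced)) == 4L, threshold >= 0)
  size <- object_size(size)
  d <- dim(enhanced)
  ts <- attr(enhanced, "ts") %||% (seq_len(d[1]) - 1L)
  recs <- list()
  for (i in seq_len(d[1])) {
    v <- enhanced[i, , , ]
    dim(v) <- d[2:4]
    m <- max(v)
    if (m <= 0) next
    hits <- .cf_local_maxima3(v, dim(v), as.numeric(size), threshold * m)
    if (nrow(hits) == 0) next
    border <- hits[, 1] < size[1] | hits[, 1] > d[2] - 1 - size[1] |
              hits[, 2] < size[2] | hits[, 2] > d[3] - 1 - size[2] |
              hits[, 3] < size[3] | hits[, 3] > d[4] - 1 - size[3]
    recs[[length(recs) + 1L]] <- data.frame(
      t = ts[i], z = as.integer(hits[, 1]), y = as.integer(hits[, 2]),
      x = as.integer(hits[, 3]), score = hits[, 4] / m, border = border)
  }
  detection_set(if (length(recs)) do.call(rbind, recs) else NULL,
                class_id = class_id)
}

#' End-to-end cell-centre detection
#'
#' Composes [predict_volume()], [hessian_enhance()] and [find_maxima()],
#' optionally restricting detections to an interpolated polygon ROI.
#'
#' @param model a `forest_model` from [train_proximity()].
#' @param vol a [volume_image()].
#' @param t 0-based timepoint(s); detections from all are pooled.
#' @param size an [object_size()] (expected cell radii in voxels).
#' @param threshold relative detection threshold (see [find_maxima()]).
#' @param roi optional [polygon_roi()] — only detections whose centroid
#'   falls inside the interpolated polygon at their `(t, z)` are kept.
#' @param min_peak minimum predicted proximity at a detection.  The
#'   threshold on the blob response is relative to the per-timepoint
#'   maximum, so on a volume with no cells it would keep noise maxima;
#'   requiring the proximity map itself to support the detection (a true
#'   centre scores near 1, background near 0) suppresses them.
#' @param class class id to detect.
#' @return a [detection_set()].
#' @export
detect_centres <- function(model, vol, t = 0, size, threshold = 0.1,
                           roi = NULL, min_peak = 0.2,
                           class = model$classes[1]) {
  vol <- normalize_volume(vol)
  parts <- lapply(t, function(tt) {
    pv <- predict_volume(model, vol, tt, class = class, normalized = TRUE)
    enh <- hessian_enhance(pv, size)
    r <- find_maxima(enh, size, threshold, class_id = class)$records
    if (nrow(r) > 0 && min_peak > 0) {
      pk <- pv$values[cbind(1L, r$z + 1L, r$y + 1L, r$x + 1L)]
      r <- r[pk >= min_peak, , drop = FALSE]
    }
    r
  })
  d <- detection_set(do.call(rbind, parts), class_id = class)
  if (!is.null(roi)) d <- filter_detections(d, roi)
  d
}
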