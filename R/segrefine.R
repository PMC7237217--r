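#' Seed detections into a crude sphere segmentation
#'
#' Places an ellipsoid of radii `h` around each detected centre; voxels
#' covered by several ellipsoids are assigned to the nearer centre (in
#' radius-scaled distance).  Labels are 1-based in detection order.
#'
#' @param d a [detection_set()] for a single timepoint.
#' @param size an [object_size()].
#' @param shape label-volume shape `c(Z, Y, X)`.
#' @return integer label array `(z, y, x)`; 0 is background.
#' @export
seeds_to_spheres <- function(d, size, shape) {
  stopifnot(inherits(d, "detection_set"))
  size <- object_size(size)
  labels <- array(0L, shape)
  r <- d$records
  if (nrow(r) == 0) return(labels)
  if (length(unique(r$t)) > 1L) stop("one timepoint at a time")
  best <- array(Inf, shape)
  for (i in seq_len(nrow(r))) {
    ctr <- c(r$z[i], r$y[i], r$x[i])
    lo <- pmax(1, floor(ctr - size) + 1)
    hi <- pmin(shape, ceiling(ctr + size) + 1)
    zs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; xs <- lo[3]:hi[3]
    q <- outer(outer(((zs - 1 - ctr[1]) / size[1])^2,
                     ((ys - 1 - ctr[2]) / size[2])^2, `+`),
               ((xs - 1 - ctr[3]) / size[3])^2, `+`)
    sub_b <- best[zs, ys, xs, drop = FALSE]
    sub_l <- labels[zs, ys, xs, drop = FALSE]
    take <- q <= 1 & q < sub_b
    sub_l[take] <- i
    sub_b[take] <- q[take]
    labels[zs, ys, xs] <- sub_l
    best[zs, ys, xs] <- sub_b
  }
  labels
}

#' Refine a crude segmentation with active contours and watershed
#'
#' Evolves the binary union of the input labels for `iterations` steps of
#' a morphological Chan-Vese active contour (region-based: voxels move to
#' the side — foreground mean vs background mean — they resemble more,
#' with one curvature-smoothing pass per iteration), then re-partitions
#' the result into instances by marker-based watershed on the inverted
#' smoothed image, seeded at the detected centres.  Marker voxels are
#' always retained, so the output label count equals the detection count.
#'
#' @param labels integer label array `(z, y, x)` (e.g. from
#'   [seeds_to_spheres()]).
#' @param image intensity array `(z, y, x)` (or a [volume_image()], first
#'   timepoint/channel), typically normalized.
#' @param centres the [detection_set()] used as watershed markers.
#' @param size an [object_size()]; sets the watershed smoothing scale
#'   (`h / 2`).
#' @param iterations active-contour iterations, default 4 (useful range
#'   about 2-6).
#' @return integer label array `(z, y, x)`.
#' @export
refine_labels <- function(labels, image, centres, size, iterations = 4) {
  if (inherits(image, "volume_image")) image <- vol_zyx(image, 0, 1)
  stopifnot(all(dim(labels) == dim(image)), iterations >= 1)
  size <- object_size(size)
  if (!any(labels > 0)) stop("empty label volume")
  u <- array(as.numeric(labels > 0), dim(labels))
  r1 <- c(1L, 1L, 1L)
  for (it in seq_len(iterations)) {
    c1 <- mean(image[u > 0])
    c0 <- if (any(u == 0)) mean(image[u == 0]) else c1
    dil <- .cf_box_extremum3(u, dim(u), r1, TRUE)
    ero <- .cf_box_extremum3(u, dim(u), r1, FALSE)
    gradu <- dil - ero  # nonzero only on the contour band
    aux <- gradu * ((image - c1)^2 - (image - c0)^2)
    u[aux < 0] <- 1
    u[aux > 0] <- 0
    # one curvature pass: alternate opening / closing
    if (it %% 2 == 1) {
      u <- .cf_box_extremum3(.cf_box_extremum3(u, dim(u), r1, FALSE),
                             dim(u), r1, TRUE)
    } else {
      u <- .cf_box_extremum3(.cf_box_extremum3(u, dim(u), r1, TRUE),
                             dim(u), r1, FALSE)
    }
  }
  rec <- centres$records
  if (length(unique(rec$t)) > 1L) stop("one timepoint at a time")
  markers <- array(0L, dim(u))
  mask <- u > 0
  for (i in seq_len(nrow(rec))) {
    idx <- cbind(rec$z[i], rec$y[i], rec$x[i]) + 1L
    markers[idx] <- i
    mask[idx] <- TRUE  # a marker always keeps its instance
  }
  sig <- as.numeric(size) / 2
  sm <- conv_sep3(image, lapply(sig, gaussian_kernel_1d, order = 0))
  .cf_marker_watershed3(-sm, dim(u), markers, mask)
}
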