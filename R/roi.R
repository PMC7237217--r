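#' Keyframed polygon ROI
#'
#' A region of interest defined by closed polygons drawn at a few keyframe
#' planes/timepoints and reconstructed at any `(t, z)` by interpolation:
#' each keyframe polygon is resampled to `n_points` vertices uniformly by
#' arc length (starting from a canonical vertex and oriented
#' counter-clockwise, so that vertices correspond across keyframes), then
#' corresponding vertices are interpolated linearly in `z` and in `t`
#' (bilinear across the two axes).  Outside the keyframed range the
#' nearest keyframe is used.
#'
#' @param keyframes list of keyframes, each `list(t =, z =, vertices =)`
#'   where `vertices` is a numeric matrix with columns `(y, x)` and at
#'   least 3 rows; at most one polygon per `(t, z)`.
#' @param n_points resampled vertex count used for correspondence.
#' @return object of class `polygon_roi`.
#' @export
polygon_roi <- function(keyframes, n_points = 100L) {
  stopifnot(length(keyframes) >= 1L)
  kf <- lapply(keyframes, function(k) {
    v <- as.matrix(k$vertices)
    if (ncol(v) != 2L || nrow(v) < 3L)
      stop("each keyframe polygon needs >= 3 (y, x) vertices")
    list(t = as.integer(k$t %||% 0L), z = as.integer(k$z %||% 0L),
         vertices = v, resampled = resample_polygon(v, n_points))
  })
  keys <- vapply(kf, function(k) paste(k$t, k$z), "")
  if (anyDuplicated(keys)) stop("at most one keyframe polygon per (t, z)")
  ord <- order(vapply(kf, `[[`, 0L, "t"), vapply(kf, `[[`, 0L, "z"))
  structure(list(keyframes = kf[ord], n_points = as.integer(n_points)),
            class = "polygon_roi")
}

#' Resample a closed polygon uniformly by arc length
#'
#' Produces `n` points along the polygon boundary, oriented
#' counter-clockwise (positive shoelace area in `(x, y)`), starting at the
#' boundary point nearest the direction of the +x axis from the polygon
#' centroid.  This canonical parameterization is what puts vertices of
#' differently drawn keyframe polygons into correspondence.
#'
#' @param vertices matrix with columns `(y, x)`.
#' @param n number of resampled points.
#' @return `n x 2` matrix `(y, x)`.
#' @export
resample_polygon <- function(vertices, n = 100L) {
  v <- as.matrix(vertices)
  if (nrow(v) < 3L) stop("degenerate polygon")
  # counter-clockwise in (x, y)
  xs <- v[, 2]; ys <- v[, 1]
  area2 <- sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)
  if (area2 < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  vc <- rbind(v, v[1, ])
  seg <- sqrt(rowSums(diff(vc)^2))
  if (sum(seg) <= 0) stop("degenerate polygon")
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  pts <- matrix(0, n, 2)
  j <- 1L
  for (i in seq_len(n)) {
    while (cum[j + 1L] < s[i] && j < length(seg)) j <- j + 1L
    f <- if (seg[j] > 0) (s[i] - cum[j]) / seg[j] else 0
    pts[i, ] <- vc[j, ] + f * (vc[j + 1L, ] - vc[j, ])
  }
  ctr <- colMeans(pts)
  ang <- atan2(pts[, 1] - ctr[1], pts[, 2] - ctr[2])  # 0 along +x
  start <- which.min(abs(ang))
  pts[c(start:n, seq_len(start - 1L)), , drop = FALSE]
}

#' Interpolate a keyframed ROI at a plane/timepoint
#'
#' @param roi a [polygon_roi()].
#' @param t,z 0-based timepoint and plane indices.
#' @return `n_points x 2` matrix `(y, x)` of the interpolated polygon.
#' @export
interpolate_roi <- function(roi, t, z) {
  stopifnot(inherits(roi, "polygon_roi"))
  kts <- vapply(roi$keyframes, `[[`, 0L, "t")
  at_time <- function(tt) {
    kf <- roi$keyframes[kts == tt]
    zs <- vapply(kf, `[[`, 0L, "z")
    if (z <= min(zs)) return(kf[[which.min(zs)]]$resampled)
    if (z >= max(zs)) return(kf[[which.max(zs)]]$resampled)
    lo <- max(zs[zs <= z]); hi <- min(zs[zs >= z])
    if (lo == hi) return(kf[[match(lo, zs)]]$resampled)
    f <- (z - lo) / (hi - lo)
    (1 - f) * kf[[match(lo, zs)]]$resampled +
      f * kf[[match(hi, zs)]]$resampled
  }
  uts <- sort(unique(kts))
  if (t <= min(uts)) return(at_time(min(uts)))
  if (t >= max(uts)) return(at_time(max(uts)))
  lo <- max(uts[uts <= t]); hi <- min(uts[uts >= t])
  if (lo == hi) return(at_time(lo))
  f <- (t - lo) / (hi - lo)
  (1 - f) * at_time(lo) + f * at_time(hi)
}

#' Even-odd point-in-polygon test (boundary inclusive)
#'
#' @param points matrix with columns `(y, x)`.
#' @param polygon matrix with columns `(y, x)` (closed implicitly).
#' @param eps tolerance for the boundary test.
#' @return logical vector.
#' @export
point_in_polygon <- function(points, polygon, eps = 1e-9) {
  pts <- matrix(as.numeric(points), ncol = 2)
  py <- polygon[, 1]; px <- polygon[, 2]
  n <- length(py)
  jj <- c(n, seq_len(n - 1L))
  vapply(seq_len(nrow(pts)), function(i) {
    y <- pts[i, 1]; x <- pts[i, 2]
    inside <- FALSE
    for (k in seq_len(n)) {
      y1 <- py[k]; x1 <- px[k]; y2 <- py[jj[k]]; x2 <- px[jj[k]]
      # boundary: point on segment
      d <- abs((x2 - x1) * (y - y1) - (y2 - y1) * (x - x1))
      len2 <- (x2 - x1)^2 + (y2 - y1)^2
      if (len2 > 0 && d * d <= eps * len2 &&
          x >= min(x1, x2) - eps && x <= max(x1, x2) + eps &&
          y >= min(y1, y2) - eps && y <= max(y1, y2) + eps)
        return(TRUE)
      if ((y1 > y) != (y2 > y) &&
          x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
        inside <- !inside
    }
    inside
  }, logical(1))
}

#' Filter detections by an interpolated ROI
#'
#' Keeps detections whose `(y, x)` centroid lies inside the ROI polygon
#' interpolated at their `(t, z)`; boundary points count as inside.
#'
#' @param d a [detection_set()].
#' @param roi a [polygon_roi()].
#' @return the filtered [detection_set()].
#' @export
filter_detections <- function(d, roi) {
  stopifnot(inherits(d, "detection_set"), inherits(roi, "polygon_roi"))
  r <- d$records
  if (nrow(r) == 0) return(d)
  keep <- logical(nrow(r))
  for (grp in split(seq_len(nrow(r)), paste(r$t, r$z))) {
    poly <- interpolate_roi(roi, r$t[grp[1]], r$z[grp[1]])
    keep[grp] <- point_in_polygon(cbind(r$y[grp], r$x[grp]), poly)
  }
  detection_set(r[keep, , drop = FALSE], class_id = d$class_id)
}

#' Read/write ROIs as structured text (JSON)
#'
#' @param roi a [polygon_roi()].
#' @param path file path.
#' @return `read_roi` returns a [polygon_roi()].
#' @export
write_roi <- function(roi, path) {
  recs <- lapply(roi$keyframes, function(k)
    list(t = k$t, z = k$z, vertices = unname(k$vertices)))
  jsonlite::write_json(list(n_points = roi$n_points, keyframes = recs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  kf <- lapply(obj$keyframes, function(k) {
    v <- k$vertices
    if (is.list(v)) v <- do.call(rbind, v)
    list(t = k$t, z = k$z, vertices = v)
  })
  polygon_roi(kf, n_points = obj$n_points %||% 100L)
}
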