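#' Multidimensional microscopy volume
#'
#' Container for intensity data over `(t, z, y, x, c)` with physical voxel
#' spacing.  All package functions consume and produce volumes in this
#' canonical axis order; use `axis_order` to describe data held in a
#' different order and it will be permuted (missing axes become singleton
#' dimensions).
#'
#' @param data numeric array with up to five dimensions.  Without
#'   `axis_order` the array must already be 5D in `(t, z, y, x, c)` order.
#' @param spacing physical voxel size `(dz, dy, dx)` in micrometres.
#' @param axis_order optional string naming `data`'s axes from
#'   `{T, Z, Y, X, C}`, e.g. `"ZYX"`.
#' @return an object of class `volume_image` with fields `data` (5D array),
#'   `spacing` and `axis_meta` (the source axis order tag).
#' @examples
#' v <- volume_image(array(runif(4 * 8 * 8), c(4, 8, 8)), axis_order = "ZYX")
#' dim(v$data)  # 1 4 8 8 1
#' @export
volume_image <- function(data, spacing = c(1, 1, 1), axis_order = NULL) {
  if (is.null(axis_order)) {
    if (!is.array(data) || length(dim(data)) != 5L)
      stop("without `axis_order`, `data` must be a 5D (t,z,y,x,c) array")
  } else {
    data <- canonicalize_axes(data, axis_order)
  }
  if (!is.numeric(data)) stop("`data` must be numeric")
  if (any(!is.finite(data))) stop("`data` contains non-finite values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three positive values (dz, dy, dx)")
  structure(list(data = data, spacing = spacing,
                 axis_meta = if (is.null(axis_order)) "TZYXC" else axis_order),
            class = "volume_image")
}

#' Permute an array into canonical (t, z, y, x, c) order
#'
#' @param data numeric array (or matrix/vector for 2D/1D inputs).
#' @param axis_order string naming `data`'s axes, a subset of `"TZYXC"`;
#'   its length must equal the number of dimensions of `data`.  Axes not
#'   named become singleton dimensions.  Idempotent for `"TZYXC"` input.
#' @return 5D array in `(t, z, y, x, c)` order.
#' @export
canonicalize_axes <- function(data, axis_order) {
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  d <- dim(data)
  letters5 <- c("T", "Z", "Y", "X", "C")
  ax <- strsplit(toupper(axis_order), "")[[1]]
  if (length(ax) != length(d))
    stop(sprintf("axis_order '%s' names %d axes but data has %d dimensions",
                 axis_order, length(ax), length(d)))
  if (anyDuplicated(ax) || !all(ax %in% letters5))
    stop("axis_order must be distinct letters from T, Z, Y, X, C")
  # permute present axes into canonical relative order, then pad
  perm <- order(match(ax, letters5))
  data <- aperm(data, perm)
  full <- rep(1L, 5)
  full[match(sort(match(ax, letters5)), seq_len(5))] <- dim(data)
  array(data, dim = full)
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "volume_image: t=%d z=%d y=%d x=%d c=%d | spacing (dz,dy,dx) = %s um\n",
    d[1], d[2], d[3], d[4], d[5], paste(signif(x$spacing, 3), collapse = ", ")))
  invisible(x)
}

#' Load a (multipage) TIFF as a volume
#'
#' Reads a 2D image or a multipage TIFF stack and arranges it into
#' canonical `(t, z, y, x, c)` order.  Within a page the axes are `(y, x)`
#' (or `(y, x, c)` for files with per-page samples); the remaining letters
#' of `axis_order` describe the page ordering, leftmost slowest.  When
#' more than one non-page axis is present, supply their sizes via `sizes`
#' (one may be left out and is inferred).
#'
#' @param path TIFF file path.
#' @param axis_order axis letters of the file, e.g. `"YX"`, `"ZYX"`,
#'   `"TZYX"`, `"ZCYX"` or `"ZYXC"`.
#' @param sizes optional named integer vector giving page-axis sizes,
#'   e.g. `c(Z = 10, C = 2)`.
#' @param spacing voxel spacing `(dz, dy, dx)` recorded on the volume.
#' @return a [volume_image()].
#' @export
load_volume <- function(path, axis_order, sizes = NULL, spacing = c(1, 1, 1)) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  pages <- withCallingHandlers(
    tiff::readTIFF(path, all = TRUE, info = FALSE),
    # libtiff tags 2-sample grayscale pages as missing ExtraSamples;
    # the data itself reads back correctly
    warning = function(w) {
      if (grepl("ExtraSamples", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (!is.list(pages)) pages <- list(pages)
  ax <- strsplit(toupper(axis_order), "")[[1]]
  if (anyDuplicated(ax) || !all(ax %in% c("T", "Z", "Y", "X", "C")))
    stop("axis_order must be distinct letters from T, Z, Y, X, C")
  pd <- dim(pages[[1]])
  in_page_c <- length(pd) == 3L
  page_ax <- setdiff(ax, if (in_page_c) c("Y", "X", "C") else c("Y", "X"))
  if (!all(c("Y", "X") %in% ax))
    stop("axis_order must contain Y and X")
  if (in_page_c && !("C" %in% ax))
    stop("file stores per-page channels; axis_order must contain C")
  npages <- length(pages)
  # resolve page-axis sizes
  psz <- setNames(rep(NA_integer_, length(page_ax)), page_ax)
  if (!is.null(sizes)) psz[names(sizes)] <- as.integer(sizes)
  nun <- sum(is.na(psz))
  if (nun > 1L)
    stop("ambiguous page axes ", paste(page_ax, collapse = ","),
         ": supply `sizes` for all but one")
  if (nun == 1L)
    psz[is.na(psz)] <- npages / prod(psz[!is.na(psz)])
  if (length(psz) && (any(psz %% 1 != 0) || prod(psz) != npages))
    stop(sprintf("page-axis sizes (%s) inconsistent with %d pages",
                 paste(sprintf("%s=%s", names(psz), psz), collapse = ","),
                 npages))
  ny <- pd[1]; nx <- pd[2]
  nc <- if (in_page_c) pd[3] else if ("C" %in% page_ax) psz[["C"]] else 1L
  nt <- if ("T" %in% page_ax) psz[["T"]] else 1L
  nz <- if ("Z" %in% page_ax) psz[["Z"]] else 1L
  out <- array(0, dim = c(nt, nz, ny, nx, nc))
  # page index -> page-axis indices (mixed radix, first letter slowest)
  rad <- as.integer(psz)
  for (p in seq_len(npages)) {
    rem <- p - 1L
    idx <- integer(length(rad))
    if (length(rad)) {
      for (k in rev(seq_along(rad))) {
        idx[k] <- rem %% rad[k]
        rem <- rem %/% rad[k]
      }
    }
    gi <- function(letter) if (letter %in% page_ax) idx[match(letter, page_ax)] + 1L else 1L
    if (in_page_c) {
      out[gi("T"), gi("Z"), , , ] <- pages[[p]]
    } else {
      out[gi("T"), gi("Z"), , , gi("C")] <- pages[[p]]
    }
  }
  if (any(!is.finite(out))) stop("volume contains non-finite intensities")
  volume_image(out, spacing = spacing)
}

#' Save a volume as a multipage TIFF
#'
#' Pages are written t-slowest then z; multichannel data is stored with
#' per-page samples, i.e. axis order `"TZYXC"`.  With `bits = 32` the data
#' is written as 32-bit float and round-trips real values at single
#' precision; with 8 or 16 bits values must lie in `[0, 1]`.
#'
#' @param vol a [volume_image()].
#' @param path output path.
#' @param bits bits per sample (8, 16 or 32).
#' @export
save_volume <- function(vol, path, bits = 32) {
  stopifnot(inherits(vol, "volume_image"), bits %in% c(8, 16, 32))
  d <- dim(vol$data)
  pages <- vector("list", d[1] * d[2])
  p <- 1L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) {
    pg <- vol$data[t, z, , , , drop = FALSE]
    dim(pg) <- d[3:5]
    if (d[5] == 1L) dim(pg) <- d[3:4]
    pages[[p]] <- pg
    p <- p + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Percentile-normalize a volume
#'
#' Rescales each `(t, c)` sub-volume to `[0, 1]` by clipping at the lower
#' and upper intensity percentiles, making training and prediction robust
#' to brightness differences and hot pixels between acquisitions.  Called
#' internally before any feature computation.
#'
#' @param vol a [volume_image()].
#' @param probs lower/upper clip percentiles (defaults 0.1% and 99.9%).
#' @return a normalized [volume_image()].
#' @export
normalize_volume <- function(vol, probs = c(0.001, 0.999)) {
  stopifnot(inherits(vol, "volume_image"))
  d <- dim(vol$data)
  out <- vol$data
  for (t in seq_len(d[1])) for (ch in seq_len(d[5])) {
    sub <- out[t, , , , ch]
    q <- quantile(sub, probs, names = FALSE)
    rng <- q[2] - q[1]
    sub <- if (rng <= 0) sub * 0 else pmin(1, pmax(0, (sub - q[1]) / rng))
    out[t, , , , ch] <- sub
  }
  vol$data <- out
  vol
}

# Extract one (z, y, x) sub-array for a timepoint/channel.
vol_zyx <- function(vol, t = 0, channel = 1) {
  d <- dim(vol$data)
  a <- vol$data[t + 1L, , , , channel]
  dim(a) <- d[2:4]
  a
}

# Extract one (y, x, c) plane for a timepoint/z.
vol_plane <- function(vol, t = 0, z = 0) {
  d <- dim(vol$data)
  a <- vol$data[t + 1L, z + 1L, , , ]
  dim(a) <- d[c(3, 4, 5)]
  a
}
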