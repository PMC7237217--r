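#' Phantom specification
#'
#' Parameters of the synthetic 3D(+T) phantom: clustered spherical cells
#' with soft (Gaussian-blurred) edges, constant foreground amplitude and
#' additive Gaussian noise at a controlled signal-to-noise ratio.  The
#' defaults emulate a low-SNR, highly clustered (75%) nuclei benchmark:
#' 30 cells of radius 8 voxels in a 40 x 128 x 128 volume at SNR 5.
#'
#' SNR is defined here as foreground amplitude divided by the noise
#' standard deviation.
#'
#' @param shape volume shape `c(Z, Y, X)` in voxels.
#' @param n_cells number of cells.
#' @param radius mean cell radius in voxels.
#' @param radius_jitter fractional radius jitter (uniform).
#' @param clustering fraction of cells placed touching an existing cell
#'   (centre distance ~ sum of radii); the rest are placed uniformly with
#'   non-overlap.
#' @param snr signal-to-noise ratio (> 0).
#' @param amplitude foreground amplitude.
#' @param n_timepoints number of frames.
#' @param motion_sd per-frame random-walk displacement sd in voxels
#'   (0 = static).
#' @param n_channels 1, or 2 for a nuclear sphere plus cytoplasmic-shell
#'   second channel.
#' @param division_schedule optional list (one entry per cell) of 0-based
#'   frames at which that cell divides; used by
#'   [generate_division_series()].
#' @param seed RNG seed; the same seed reproduces the phantom bit-exactly.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(40, 128, 128), n_cells = 30, radius = 8,
                         radius_jitter = 0.1, clustering = 0.75, snr = 5,
                         amplitude = 1, n_timepoints = 1, motion_sd = 0,
                         n_channels = 1, division_schedule = NULL, seed = 0) {
  stopifnot(length(shape) == 3L, all(shape >= 1), n_cells >= 0, radius > 0,
            clustering >= 0, clustering <= 1, snr > 0,
            n_timepoints >= 1, n_channels %in% 1:2)
  if (n_cells > 0 && any(2 * radius * (1 + radius_jitter) >= shape))
    stop("cells do not fit inside the volume")
  structure(list(shape = as.integer(shape), n_cells = as.integer(n_cells),
                 radius = radius, radius_jitter = radius_jitter,
                 clustering = clustering, snr = snr, amplitude = amplitude,
                 n_timepoints = as.integer(n_timepoints),
                 motion_sd = motion_sd, n_channels = as.integer(n_channels),
                 division_schedule = division_schedule,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Draw a solid sphere (max-composited) into a (z, y, x) canvas.
add_sphere <- function(canvas, centre, radius, amplitude) {
  d <- dim(canvas)
  lo <- pmax(1, floor(centre - radius) + 1)
  hi <- pmin(d, ceiling(centre + radius) + 1)
  zs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; xs <- lo[3]:hi[3]
  dz2 <- (zs - 1 - centre[1])^2
  dy2 <- (ys - 1 - centre[2])^2
  dx2 <- (xs - 1 - centre[3])^2
  d2 <- outer(outer(dz2, dy2, `+`), dx2, `+`)
  sub <- canvas[zs, ys, xs, drop = FALSE]
  canvas[zs, ys, xs] <- pmax(sub, amplitude * (d2 <= radius^2))
  canvas
}

# Draw an ellipsoid with long in-plane axis along unit vector (uy, ux).
add_spindle <- function(canvas, centre, radius, axis_yx, amplitude,
                        elong = 1.6, short = 0.6) {
  d <- dim(canvas)
  a_long <- elong * radius; a_short <- short * radius
  ext <- a_long
  lo <- pmax(1, floor(centre - ext) + 1)
  hi <- pmin(d, ceiling(centre + ext) + 1)
  zs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; xs <- lo[3]:hi[3]
  gz <- zs - 1 - centre[1]; gy <- ys - 1 - centre[2]; gx <- xs - 1 - centre[3]
  # in-plane projections onto the long / perpendicular axes
  py <- axis_yx[1]; px <- axis_yx[2]
  arr <- array(0, c(length(zs), length(ys), length(xs)))
  for (iz in seq_along(gz)) {
    L <- outer(gy * py, gx * px, `+`)          # projection on long axis
    P <- outer(gy * px, -gx * py, `+`)         # perpendicular in-plane
    q <- (L / a_long)^2 + (P / a_short)^2 + (gz[iz] / a_short)^2
    arr[iz, , ] <- amplitude * (q <= 1)
  }
  sub <- canvas[zs, ys, xs, drop = FALSE]
  canvas[zs, ys, xs] <- pmax(sub, arr)
  canvas
}

# Place n_cells centres; returns data.frame(cell, z, y, x, radius).
place_cells <- function(spec) {
  n <- spec$n_cells
  if (n == 0)
    return(data.frame(cell = integer(0), z = numeric(0), y = numeric(0),
                      x = numeric(0), radius = numeric(0)))
  radii <- spec$radius *
    (1 + runif(n, -spec$radius_jitter, spec$radius_jitter))
  sh <- spec$shape
  pos <- matrix(NA_real_, n, 3)
  unif_pos <- function(r) vapply(1:3, function(a) runif(1, r, sh[a] - 1 - r), 0)
  n_touch <- round(spec$clustering * n)
  touch_idx <- if (n_touch > 0 && n > 1) 1 + seq_len(min(n_touch, n - 1))
               else integer(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(500)) {
      if (i %in% touch_idx) {
        j <- sample.int(i - 1L, 1)
        dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
        p <- pos[j, ] + dir * (radii[i] + radii[j]) * runif(1, 1.0, 1.1)
        if (any(p < radii[i]) || any(p > sh - 1 - radii[i])) next
        lim <- 0.95  # touching placements may brush their anchor
      } else {
        p <- unif_pos(radii[i])
        lim <- 1.0
      }
      if (i > 1) {
        dd <- sqrt(rowSums(sweep(pos[seq_len(i - 1), , drop = FALSE],
                                 2, p)^2))
        if (any(dd < lim * (radii[i] + radii[seq_len(i - 1)]))) next
      }
      pos[i, ] <- p
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place ", n, " cells without overlap; ",
           "reduce n_cells or clustering")
  }
  data.frame(cell = seq_len(n), z = pos[, 1], y = pos[, 2], x = pos[, 3],
             radius = radii)
}

# Blur + noise finishing applied per (t, channel) canvas.
finish_canvas <- function(canvas, spec) {
  k <- gaussian_kernel_1d(spec$radius / 4, 0)
  canvas <- conv_sep3(canvas, list(k, k, k))
  canvas + rnorm(length(canvas), 0, spec$amplitude / spec$snr)
}

#' Generate a synthetic phantom volume
#'
#' Renders clustered solid spheres with Gaussian-blurred edges (blur sigma
#' = radius / 4), constant foreground amplitude `A`, and additive Gaussian
#' noise of sd `A / snr`.  Returns the exact ground-truth centres.
#' Reproducible: the same spec (including seed) yields a bit-identical
#' volume.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a [volume_image()]), `truth` (data.frame
#'   `t, cell, z, y, x, radius` with 0-based real-valued coordinates, one
#'   block per timepoint) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  cells <- place_cells(spec)
  sh <- spec$shape
  nt <- spec$n_timepoints
  data <- array(0, c(nt, sh, spec$n_channels))
  truth <- list()
  for (t in seq_len(nt)) {
    if (t > 1 && spec$motion_sd > 0 && nrow(cells) > 0) {
      step <- matrix(rnorm(nrow(cells) * 3, 0, spec$motion_sd),
                     ncol = 3)
      for (a in 1:3)
        cells[[c("z", "y", "x")[a]]] <-
          pmin(sh[a] - 1 - cells$radius,
               pmax(cells$radius, cells[[c("z", "y", "x")[a]]] + step[, a]))
    }
    canvas <- array(0, sh)
    for (i in seq_len(nrow(cells)))
      canvas <- add_sphere(canvas, unlist(cells[i, c("z", "y", "x")]),
                           cells$radius[i], spec$amplitude)
    data[t, , , , 1] <- finish_canvas(canvas, spec)
    if (spec$n_channels == 2) {
      shell <- array(0, sh)
      for (i in seq_len(nrow(cells))) {
        ctr <- unlist(cells[i, c("z", "y", "x")])
        shell <- add_sphere(shell, ctr, 1.2 * cells$radius[i],
                            spec$amplitude)
        shell <- shell - add_sphere(array(0, sh), ctr, cells$radius[i],
                                    spec$amplitude)
      }
      data[t, , , , 2] <- finish_canvas(pmax(shell, 0), spec)
    }
    if (nrow(cells))
      truth[[t]] <- data.frame(t = t - 1L, cells)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(t = integer(0), cell = integer(0), z = numeric(0),
               y = numeric(0), x = numeric(0), radius = numeric(0))
  rownames(truth) <- NULL
  list(volume = volume_image(data), truth = truth, spec = spec)
}

#' Generate a time series with scheduled cell divisions
#'
#' Each dividing cell shows, at every scheduled division frame `d`, a
#' transient elongated spindle-like figure (brighter, 2 frames: `d` and
#' `d + 1`) in place of its sphere; afterwards the mother persists in
#' place and a small daughter appears adjacent for a few frames.  The
#' mitotic figure is rendered brighter than interphase cells, as
#' condensed chromatin and spindle are in live recordings — that contrast
#' is what a "dividing" class regressor learns.
#'
#' @param spec a [phantom_spec()] with `n_timepoints > 1` and
#'   `division_schedule` (list of 0-based division frames per cell; `NULL`
#'   entries or an absent schedule give a static series).
#' @return list with `volume`, `truth` (mother centres per frame),
#'   `events` (data.frame `cell, t` of scheduled divisions) and `spec`.
#' @export
generate_division_series <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nt <- spec$n_timepoints
  sched <- spec$division_schedule
  if (!is.null(sched)) {
    stopifnot(length(sched) == spec$n_cells)
    for (s in sched)
      if (length(s) && (any(s < 0) || any(s >= nt) || anyDuplicated(s) ||
                        any(diff(sort(s)) < 3)))
        stop("division schedule times must be distinct, >= 3 frames apart, ",
             "within [0, n_timepoints)")
  }
  set.seed(spec$seed)
  cells <- place_cells(spec)
  sh <- spec$shape
  # one fixed spindle / daughter direction per division event
  ev <- list()
  for (i in seq_len(nrow(cells))) {
    times <- if (is.null(sched)) integer(0) else sort(sched[[i]])
    for (d in times) {
      th <- runif(1, 0, 2 * pi)
      ev[[length(ev) + 1L]] <- data.frame(cell = i, t = d,
                                          uy = sin(th), ux = cos(th))
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(cell = integer(0), t = integer(0), uy = numeric(0),
               ux = numeric(0))
  daughter_life <- 6L
  data <- array(0, c(nt, sh, spec$n_channels))
  truth <- list()
  for (t0 in seq_len(nt) - 1L) {
    canvas <- array(0, sh)
    for (i in seq_len(nrow(cells))) {
      ctr <- unlist(cells[i, c("z", "y", "x")])
      r <- cells$radius[i]
      mine <- events[events$cell == i, , drop = FALSE]
      in_division <- any(t0 - mine$t >= 0 & t0 - mine$t <= 1)
      if (in_division) {
        e <- mine[t0 - mine$t >= 0 & t0 - mine$t <= 1, ][1, ]
        canvas <- add_spindle(canvas, ctr, r, c(e$uy, e$ux),
                              1.5 * spec$amplitude)
      } else {
        canvas <- add_sphere(canvas, ctr, r, spec$amplitude)
      }
      recent <- mine[t0 - mine$t >= 2 & t0 - mine$t < 2 + daughter_life, ,
                     drop = FALSE]
      for (k in seq_len(nrow(recent))) {
        off <- c(0, recent$uy[k], recent$ux[k]) * 1.4 * r
        dtr <- pmin(sh - 1 - 0.5 * r, pmax(0.5 * r, ctr + off))
        canvas <- add_sphere(canvas, dtr, 0.5 * r, spec$amplitude)
      }
    }
    data[t0 + 1L, , , , 1] <- finish_canvas(canvas, spec)
    if (nrow(cells))
      truth[[t0 + 1L]] <- data.frame(t = t0, cells)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(t = integer(0), cell = integer(0), z = numeric(0),
               y = numeric(0), x = numeric(0), radius = numeric(0))
  rownames(truth) <- NULL
  list(volume = volume_image(data),
       truth = truth,
       events = events[c("cell", "t")],
       spec = spec)
}

#' Build training annotations for a division-series phantom
#'
#' Emulates the annotation strategy for learning a "dividing" cell class
#' alongside the generic "cell" class on a sparse division-series phantom:
#' the two spindle frames of the first `n_events` scheduled divisions are
#' annotated as dividing-class positives, while daughter-adjacent and
#' interphase frames are annotated as dividing-class background — the
#' mother-plus-daughter pair looks elongated at coarse scales, so showing
#' it as background is what keeps the dividing class specific to the
#' mitotic figure.  The cell class gets positives on interphase and
#' division frames (the cell is present throughout).
#'
#' @param div result of [generate_division_series()]; intended for sparse
#'   phantoms (annotations use full-plane regions at each cell's centre
#'   plane).
#' @param n_events number of division events annotated per cell.
#' @return list of [training_annotation()] for classes `"cell"` and
#'   `"dividing"`.
#' @export
division_annotations <- function(div, n_events = 2) {
  sh <- div$spec$shape
  nt <- div$spec$n_timepoints
  region <- c(0, 0, sh[2] - 1, sh[3] - 1)
  anns <- list()
  add <- function(cls, t, z, pts)
    anns[[length(anns) + 1L]] <<-
      training_annotation(cls, t, z, region, pts)
  for (i in unique(div$events$cell)) {
    ev <- sort(div$events$t[div$events$cell == i])
    ctr <- div$truth[div$truth$t == 0 & div$truth$cell == i, ]
    zc <- round(ctr$z)
    pt <- cbind(ctr$y, ctr$x)
    use <- head(ev, n_events)
    for (e in use) {
      add("dividing", e, zc, pt)                       # spindle frames
      if (e + 1 < nt) add("dividing", e + 1, zc, pt)
      if (e + 5 < nt) add("dividing", e + 5, zc, NULL) # daughter visible
      if (e + 15 < nt) add("dividing", e + 15, zc, NULL) # interphase
      if (e + 15 < nt) add("cell", e + 15, zc, pt)
    }
    add("cell", use[1], zc, pt)
    far <- max(ev) + 13
    if (far < nt) add("dividing", far, zc, NULL)
  }
  anns
}

#' Build training annotations from phantom ground truth
#'
#' Emulates point-and-click annotation on a generated phantom: picks the
#' `n_planes` z-planes that cross the most cell centres (within `dz_tol`
#' planes) and annotates each with the in-plane `(y, x)` positions of
#' those cells over a full-plane region; optionally adds background-only
#' annotations on planes far from every cell, which teaches the regressor
#' what background looks like.
#'
#' @param phantom result of [generate_phantom()].
#' @param n_planes number of annotated planes with points.
#' @param dz_tol a cell is annotated on plane `z` when its centre is
#'   within `dz_tol` planes of `z`.
#' @param t 0-based timepoint to annotate.
#' @param class_id class label for the annotations.
#' @param n_background number of background-only annotated planes.
#' @return list of [training_annotation()].
#' @export
phantom_annotations <- function(phantom, n_planes = 4, dz_tol = 2, t = 0,
                                class_id = "cell", n_background = 1) {
  tr <- phantom$truth[phantom$truth$t == t, , drop = FALSE]
  sh <- phantom$spec$shape
  region <- c(0, 0, sh[2] - 1, sh[3] - 1)
  counts <- vapply(seq_len(sh[1]) - 1L,
                   function(z) sum(abs(tr$z - z) <= dz_tol), 0L)
  anns <- list()
  for (z in head(order(-counts), n_planes)) {
    sel <- abs(tr$z - (z - 1)) <= dz_tol
    pts <- if (any(sel)) cbind(tr$y[sel], tr$x[sel]) else NULL
    anns[[length(anns) + 1L]] <-
      training_annotation(class_id, t, z - 1L, region, pts)
  }
  if (n_background > 0) {
    far <- vapply(seq_len(sh[1]) - 1L,
                  function(z) all(abs(tr$z - z) > max(tr$radius, 1)), TRUE)
    for (z in head(which(far), n_background))
      anns[[length(anns) + 1L]] <-
        training_annotation(class_id, t, z - 1L, region, NULL)
  }
  anns
}
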