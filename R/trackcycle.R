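#' Link detections over time into tracks
#'
#' Frame-to-frame one-to-one assignment minimizing total displacement
#' among (track, detection) pairs within `max_disp` voxels of the track's
#' predicted position (last position, linearly extrapolated across gaps
#' when the track has at least two points).  Unmatched detections start
#' new tracks; a track is closed after `max_gap` consecutive missed
#' frames.  Linking is deterministic and invariant to the input order of
#' detections.
#'
#' @param detections a [detection_set()] spanning one or more timepoints.
#' @param max_disp maximum displacement per frame, voxels.
#' @param max_gap number of missing frames a track may bridge.
#' @return list of tracks, each a data.frame `t, z, y, x` (0-based voxel
#'   coordinates, strictly increasing `t`), ordered by track start.
#' @export
link_tracks <- function(detections, max_disp, max_gap = 0) {
  stopifnot(inherits(detections, "detection_set"), max_disp > 0)
  r <- detections$records
  if (nrow(r) == 0) return(list())
  r <- r[order(r$t, r$z, r$y, r$x), , drop = FALSE]
  frames <- min(r$t):max(r$t)
  active <- list()  # each: points (df), missed
  done <- list()
  for (f in frames) {
    det <- r[r$t == f, c("t", "z", "y", "x"), drop = FALSE]
    if (length(active)) {
      pred <- t(vapply(active, function(tr) {
        p <- tr$points
        n <- nrow(p)
        last <- as.numeric(p[n, c("z", "y", "x")])
        ahead <- f - p$t[n]
        if (n >= 2) {
          v <- (last - as.numeric(p[n - 1, c("z", "y", "x")])) /
            (p$t[n] - p$t[n - 1])
          last + v * ahead
        } else last
      }, numeric(3)))
      if (nrow(det)) {
        m <- match_within(pred, cbind(det$z, det$y, det$x),
                          rep(max_disp, 3))
      } else {
        m <- data.frame(pred_index = integer(0), truth_index = integer(0))
      }
      matched_tr <- m$pred_index
      matched_det <- m$truth_index
      for (k in seq_along(matched_tr)) {
        i <- matched_tr[k]
        active[[i]]$points <- rbind(active[[i]]$points,
                                    det[matched_det[k], ])
        active[[i]]$missed <- 0L
      }
      drop <- logical(length(active))
      for (i in setdiff(seq_along(active), matched_tr)) {
        active[[i]]$missed <- active[[i]]$missed + 1L
        if (active[[i]]$missed > max_gap) {
          done[[length(done) + 1L]] <- active[[i]]$points
          drop[i] <- TRUE
        }
      }
      active <- active[!drop]
      new_idx <- setdiff(seq_len(nrow(det)), matched_det)
    } else {
      new_idx <- seq_len(nrow(det))
    }
    for (i in new_idx)
      active[[length(active) + 1L]] <-
        list(points = det[i, , drop = FALSE], missed = 0L)
  }
  for (tr in active) done[[length(done) + 1L]] <- tr$points
  done <- lapply(done, function(p) { rownames(p) <- NULL; p })
  done[order(vapply(done, function(p) p$t[1], 0),
             vapply(done, function(p) p$z[1], 0),
             vapply(done, function(p) p$y[1], 0))]
}

#' Division signal along a track
#'
#' Samples the "dividing-cell" proximity map along a track (maximum within
#' a 3x3x3 voxel neighbourhood of the tracked position per frame; gaps are
#' filled by linear interpolation of the position), removes slow spatial
#' background differences by subtracting a centred moving average of width
#' `window` frames (edges use truncated windows), and calls division
#' events at local maxima of the background-subtracted signal that exceed
#' `threshold_mad` times its median absolute deviation, separated by at
#' least `refractory` frames.
#'
#' @param pv a [proximity_volume()] time series for the dividing class.
#' @param track a track data.frame `t, z, y, x` from [link_tracks()].
#' @param window moving-average width in frames, odd, default 21.
#' @param frame_interval minutes per frame (sets cycle-length units).
#' @param threshold_mad event threshold in MADs of the signal.
#' @param refractory minimum event separation in frames (default
#'   `floor(window / 2)`).
#' @return object of class `division_signal`: per-frame `t`, `raw`,
#'   `signal`, detected `events` (0-based frames) and `cycle_lengths`
#'   (minutes).  The automatic event rule is a package choice; inspect
#'   `signal` when working with real recordings.
#' @export
division_signal <- function(pv, track, window = 21, frame_interval = 1,
                            threshold_mad = 3, refractory = NULL) {
  stopifnot(inherits(pv, "proximity_volume"),
            window >= 3, window %% 2 == 1)
  if (is.null(refractory)) refractory <- floor(window / 2)
  d <- dim(pv$values)
  ts <- track$t[1]:track$t[nrow(track)]
  pos <- if (nrow(track) == 1L) {
    matrix(as.numeric(track[1, c("z", "y", "x")]), 1, 3)
  } else {
    matrix(vapply(c("z", "y", "x"), function(a)
      approx(track$t, track[[a]], xout = ts)$y, numeric(length(ts))),
      ncol = 3)
  }
  raw <- numeric(length(ts))
  for (i in seq_along(ts)) {
    ti <- match(ts[i], pv$ts)
    if (is.na(ti)) { raw[i] <- NA; next }
    ctr <- round(pos[i, ]) + 1L
    zs <- max(1, ctr[1] - 1):min(d[2], ctr[1] + 1)
    ys <- max(1, ctr[2] - 1):min(d[3], ctr[2] + 1)
    xs <- max(1, ctr[3] - 1):min(d[4], ctr[3] + 1)
    raw[i] <- max(pv$values[ti, zs, ys, xs])
  }
  ma <- moving_average(raw, window)
  signal <- raw - ma
  events <- integer(0)
  if (length(signal) >= 3) {
    # raw median absolute deviation (no consistency scaling): the signal
    # is pulse-like, not Gaussian, and the unscaled MAD tracks the
    # baseline fluctuation
    thr <- threshold_mad * mad(signal, constant = 1, na.rm = TRUE)
    cand <- which(signal > thr &
                  signal >= c(-Inf, signal[-length(signal)]) &
                  signal >= c(signal[-1], -Inf))
    for (i in cand[order(-signal[cand])]) {
      if (all(abs(i - events) >= refractory)) events <- c(events, i)
    }
    events <- sort(events)
  }
  ev_t <- ts[events]
  structure(list(t = ts, raw = raw, signal = signal,
                 events = ev_t,
                 cycle_lengths = diff(ev_t) * frame_interval,
                 frame_interval = frame_interval,
                 window = window),
            class = "division_signal")
}

# Centred moving average with truncated windows at the edges.
moving_average <- function(x, window) {
  h <- floor(window / 2)
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - h):min(n, i + h)], na.rm = TRUE), 0)
}

#' Cell-cycle summary statistics
#'
#' Summarizes division signals into per-cell mean cycle lengths and a
#' per-sample mean, sd, and division rate.  Cells with fewer than two
#' detected divisions are excluded (a single division gives no interval).
#'
#' @param signals list of [division_signal()] objects.
#' @return list with `per_cell` (data.frame `cell, n_events, mean_cycle`),
#'   `mean_cycle` and `sd_cycle` (minutes) over qualifying cells, and
#'   `divisions_per_hour = 60 / mean_cycle`.
#' @export
cycle_stats <- function(signals) {
  rows <- lapply(seq_along(signals), function(i) {
    s <- signals[[i]]
    data.frame(cell = i, n_events = length(s$events),
               mean_cycle = if (length(s$cycle_lengths))
                 mean(s$cycle_lengths) else NA_real_)
  })
  per <- do.call(rbind, rows)
  ok <- per$n_events >= 2
  if (!any(ok))
    stop("no cell divided at least twice; cycle lengths are undefined")
  mc <- mean(per$mean_cycle[ok])
  list(per_cell = per,
       n_cells = sum(ok),
       mean_cycle = mc,
       sd_cycle = if (sum(ok) > 1) sd(per$mean_cycle[ok]) else 0,
       divisions_per_hour = 60 / mc)
}
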