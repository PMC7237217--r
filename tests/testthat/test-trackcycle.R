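make_dets <- function(df) detection_set(cbind(df, score = 0.9))

test_that("a stationary detection yields one full-length track", {
  df <- data.frame(t = 0:9, z = 5L, y = 10L, x = 10L)
  tracks <- link_tracks(make_dets(df), max_disp = 3)
  expect_equal(length(tracks), 1L)
  expect_equal(nrow(tracks[[1]]), 10L)
  expect_equal(tracks[[1]]$t, 0:9)
})

test_that("tracks terminate rather than follow jumps beyond max_disp", {
  # both cells jump 20 voxels in one frame; links must break, not stretch
  df <- data.frame(t = rep(0:3, each = 2),
                   z = 5L,
                   y = c(10, 30, 10, 30, 50, 70, 50, 70),
                   x = 10L)
  tracks <- link_tracks(make_dets(df), max_disp = 5)
  expect_equal(length(tracks), 4L)
  expect_true(all(vapply(tracks, nrow, 0L) == 2L))
})

test_that("linking is permutation-invariant and bridges gaps", {
  df <- data.frame(t = c(0, 1, 3, 4), z = 5L, y = c(10, 12, 16, 18),
                   x = 10L)
  tracks <- link_tracks(make_dets(df), max_disp = 4, max_gap = 1)
  expect_equal(length(tracks), 1L)  # gap at t = 2 bridged by extrapolation
  expect_equal(tracks[[1]]$t, c(0, 1, 3, 4))
  # no gap allowance: the track splits
  tracks0 <- link_tracks(make_dets(df), max_disp = 4, max_gap = 0)
  expect_equal(length(tracks0), 2L)
  # shuffled input order gives identical tracks
  sh <- df[sample(nrow(df)), ]
  expect_equal(link_tracks(make_dets(sh), max_disp = 4, max_gap = 1), tracks)
})

test_that("random-walking cells are tracked to their true identities", {
  set.seed(15)
  n <- 5; nf <- 50
  # cells drift in bounded boxes around well-separated anchors, so track
  # identity is unambiguous (anchors 20 apart, drift clamped to +/- 4)
  anchor <- cbind(20, 20, seq(10, 90, by = 20))
  pos <- anchor
  rows <- list()
  paths <- array(0, c(nf, n, 3))
  for (f in seq_len(nf)) {
    if (f > 1) {
      pos <- pos + matrix(rnorm(n * 3, 0, 1), ncol = 3)
      pos <- pmax(anchor - 4, pmin(anchor + 4, pos))
    }
    paths[f, , ] <- pos
    rows[[f]] <- data.frame(t = f - 1L, z = round(pos[, 1]),
                            y = round(pos[, 2]), x = round(pos[, 3]))
  }
  df <- do.call(rbind, rows)
  tracks <- link_tracks(make_dets(df), max_disp = 6)
  expect_equal(length(tracks), n)
  expect_true(all(vapply(tracks, nrow, 0L) == nf))
  # each track follows a single true cell throughout
  for (tr in tracks) {
    d0 <- sqrt(rowSums((paths[1, , ] -
                        matrix(as.numeric(tr[1, c("z", "y", "x")]),
                               n, 3, byrow = TRUE))^2))
    id <- which.min(d0)
    err <- sqrt(rowSums((paths[tr$t + 1, id, ] -
                         as.matrix(tr[c("z", "y", "x")]))^2))
    expect_lt(max(err), 1.5)
  }
})

test_that("constant series give zero signal and no events", {
  pv <- proximity_volume(array(0.4, c(30, 4, 8, 8)))
  track <- data.frame(t = 0:29, z = 2L, y = 4L, x = 4L)
  ds <- division_signal(pv, track, window = 11, frame_interval = 2)
  expect_equal(max(abs(ds$signal)), 0, tolerance = 1e-12)
  expect_equal(length(ds$events), 0L)
})

test_that("pulse trains yield the scheduled cycle length", {
  nf <- 120
  vals <- array(0.1, c(nf, 4, 8, 8))
  pulses <- seq(10, 115, by = 45)
  vals[pulses + 1, 2, 4, 4] <- 0.9
  pv <- proximity_volume(vals)
  track <- data.frame(t = 0:(nf - 1), z = 1L, y = 3L, x = 3L)
  ds <- division_signal(pv, track, window = 21, frame_interval = 2)
  expect_equal(ds$events, pulses)
  expect_equal(unique(ds$cycle_lengths), 90)  # 45 frames x 2 min
  st <- cycle_stats(list(ds))
  expect_equal(st$mean_cycle, 90)
  expect_equal(st$divisions_per_hour, 60 / 90, tolerance = 1e-12)
})

test_that("event spacing is invariant to slow background drift", {
  nf <- 120
  pulses <- seq(10, 115, by = 45)
  base <- rep(0.1, nf)
  base[pulses + 1] <- 0.9
  drift <- 0.2 * sin(seq(0, pi, length.out = nf))  # period >> window
  vals <- array(0, c(nf, 4, 8, 8))
  for (f in seq_len(nf)) vals[f, , , ] <- base[f] + drift[f]
  pv <- proximity_volume(pmin(vals, 1))
  track <- data.frame(t = 0:(nf - 1), z = 1L, y = 3L, x = 3L)
  ds <- division_signal(pv, track, window = 21, frame_interval = 2)
  expect_equal(ds$events, pulses)
})

test_that("cycle statistics enforce the two-division exclusion rule", {
  one <- structure(list(t = 0:50, raw = rep(0, 51), signal = rep(0, 51),
                        events = c(10), cycle_lengths = numeric(0),
                        frame_interval = 2, window = 21),
                   class = "division_signal")
  expect_error(cycle_stats(list(one)), "divided at least twice")
  two <- one; two$events <- c(10, 40); two$cycle_lengths <- 60
  st <- cycle_stats(list(one, two))
  expect_equal(st$n_cells, 1L)          # the once-divided cell is excluded
  expect_equal(st$mean_cycle, 60)
})

test_that("scheduled division populations are recovered without bias", {
  set.seed(16)
  true_cycles <- round(rnorm(10, 45, 7))  # frames between divisions
  sigs <- lapply(true_cycles, function(cl) {
    nf <- 150
    pulses <- seq(5, nf - 5, by = cl)
    vals <- array(0.05, c(nf, 2, 4, 4))
    vals[pulses + 1, 1, 2, 2] <- 0.8
    pv <- proximity_volume(vals)
    division_signal(pv, data.frame(t = 0:(nf - 1), z = 0L, y = 1L, x = 1L),
                    window = 21, frame_interval = 2)
  })
  st <- cycle_stats(sigs)
  sem <- sd(2 * true_cycles) / sqrt(length(true_cycles))
  expect_lt(abs(st$mean_cycle - mean(2 * true_cycles)), 2 * sem + 1e-9)
})
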