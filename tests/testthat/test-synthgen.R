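test_that("phantoms are reproducible and respect the empty case", {
  sp <- phantom_spec(shape = c(16, 48, 48), n_cells = 5, radius = 5,
                    snr = 5, seed = 3)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth, b$truth)
  # zero cells: pure noise, empty ground truth
  nz <- generate_phantom(phantom_spec(shape = c(8, 32, 32), n_cells = 0,
                                      snr = 4, seed = 1))
  expect_equal(nrow(nz$truth), 0L)
  expect_equal(mean(nz$volume$data), 0, tolerance = 0.01)
})

test_that("measured SNR matches the requested SNR within 10%", {
  for (snr in c(3, 5, 10)) {
    sp <- phantom_spec(shape = c(24, 80, 80), n_cells = 8, clustering = 0,
                       snr = snr, seed = 7)
    ph <- generate_phantom(sp)
    v <- ph$volume$data[1, , , , 1]
    tr <- ph$truth
    # foreground: deep sphere interiors; background: far from every cell
    fg <- bg <- array(FALSE, dim(v))
    idx <- which(!fg, arr.ind = TRUE)
    d2min <- rep(Inf, nrow(idx))
    for (i in seq_len(nrow(tr))) {
      d2 <- (idx[, 1] - 1 - tr$z[i])^2 + (idx[, 2] - 1 - tr$y[i])^2 +
        (idx[, 3] - 1 - tr$x[i])^2
      d2min <- pmin(d2min, d2 / tr$radius[i]^2)
    }
    fg <- d2min <= 0.25   # within r/2 of a centre
    bg <- d2min >= 4      # farther than 2r from every centre
    measured <- (mean(v[fg]) - mean(v[bg])) / sd(v[bg])
    expect_equal(measured, snr, tolerance = 0.1)
  }
})

test_that("the clustering fraction controls touching placements", {
  sp <- phantom_spec(shape = c(40, 128, 128), n_cells = 30, clustering = 0.75,
                     snr = 5, seed = 5)
  tr <- generate_phantom(sp)$truth
  pos <- as.matrix(tr[c("z", "y", "x")])
  dd <- as.matrix(dist(pos))
  diag(dd) <- Inf
  n_touching <- sum(apply(dd, 1, min) <= 2.2 * mean(tr$radius))
  expect_gte(n_touching, 0.75 * 30)
  # unclustered phantoms have no overlapping pair
  sp0 <- phantom_spec(shape = c(40, 128, 128), n_cells = 15, clustering = 0,
                      snr = 5, seed = 6)
  tr0 <- generate_phantom(sp0)$truth
  d0 <- as.matrix(dist(as.matrix(tr0[c("z", "y", "x")])))
  diag(d0) <- Inf
  rsum <- outer(tr0$radius, tr0$radius, `+`)
  expect_true(all(d0 >= rsum - 1e-9))
})

test_that("impossible packings raise an error", {
  expect_error(generate_phantom(phantom_spec(shape = c(18, 20, 20),
                                             n_cells = 40, radius = 4,
                                             snr = 5, seed = 1)),
               "without overlap")
  expect_error(phantom_spec(shape = c(8, 8, 8), n_cells = 1, radius = 6),
               "fit")
})

test_that("division series echo their schedule and support the empty case", {
  sp <- phantom_spec(shape = c(10, 40, 40), n_cells = 1, radius = 4,
                     radius_jitter = 0, clustering = 0, snr = 8,
                     n_timepoints = 95, seed = 2,
                     division_schedule = list(c(2, 47, 92)))
  dv <- generate_division_series(sp)
  expect_equal(dv$events$t, c(2, 47, 92))
  expect_equal(diff(dv$events$t), c(45, 45))
  expect_equal(dim(dv$volume$data)[1], 95L)
  # no schedule: static series, zero events
  sp0 <- phantom_spec(shape = c(10, 40, 40), n_cells = 1, radius = 4,
                      snr = 8, n_timepoints = 5, seed = 2)
  dv0 <- generate_division_series(sp0)
  expect_equal(nrow(dv0$events), 0L)
  expect_equal(dv0$volume$data[1, , , , 1], dv0$volume$data[3, , , , 1],
               tolerance = 0.5)  # same structure, different noise
  # invalid schedules are rejected
  expect_error(generate_division_series(
    phantom_spec(shape = c(10, 40, 40), n_cells = 1, radius = 4, snr = 8,
                 n_timepoints = 10, seed = 1,
                 division_schedule = list(c(5, 20)))), "within")
})

test_that("the mitotic figure is brighter and elongated versus interphase", {
  sp <- phantom_spec(shape = c(12, 40, 40), n_cells = 1, radius = 5,
                     radius_jitter = 0, clustering = 0, snr = 100,
                     n_timepoints = 8, seed = 4,
                     division_schedule = list(3))
  dv <- generate_division_series(sp)
  ctr <- round(as.numeric(dv$truth[1, c("z", "y", "x")])) + 1
  inter <- dv$volume$data[1, ctr[1], ctr[2], ctr[3], 1]
  mito <- dv$volume$data[4, ctr[1], ctr[2], ctr[3], 1]
  expect_gt(mito, 1.3 * inter)
  # a small daughter appears adjacent after the division
  post <- dv$volume$data[7, ctr[1], , , 1]
  ring <- post[abs(row(post) - ctr[2]) <= 9 & abs(col(post) - ctr[3]) <= 9 &
               (abs(row(post) - ctr[2]) > 5 | abs(col(post) - ctr[3]) > 5)]
  expect_gt(max(ring), 0.5)
})

test_that("two-channel phantoms add a cytoplasmic shell channel", {
  sp <- phantom_spec(shape = c(16, 48, 48), n_cells = 3, radius = 5,
                     clustering = 0, snr = 20, n_channels = 2, seed = 9)
  ph <- generate_phantom(sp)
  expect_equal(dim(ph$volume$data)[5], 2L)
  ctr <- round(as.numeric(ph$truth[1, c("z", "y", "x")])) + 1
  # nuclear channel bright at the centre, shell channel bright at radius
  expect_gt(ph$volume$data[1, ctr[1], ctr[2], ctr[3], 1], 0.5)
  expect_lt(ph$volume$data[1, ctr[1], ctr[2], ctr[3], 2], 0.5)
})
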