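test_that("axis canonicalization promotes and permutes correctly", {
  # 2D grayscale plane
  v <- volume_image(matrix(runif(64 * 64), 64), axis_order = "YX")
  expect_equal(dim(v$data), c(1, 1, 64, 64, 1))
  # (Z, C, Y, X) with 2 channels
  a <- array(runif(3 * 2 * 8 * 10), c(3, 2, 8, 10))
  v2 <- volume_image(a, axis_order = "ZCYX")
  expect_equal(dim(v2$data), c(1, 3, 8, 10, 2))
  expect_equal(v2$data[1, 2, 5, 7, 1], a[2, 1, 5, 7])
  expect_equal(v2$data[1, 3, 1, 9, 2], a[3, 2, 1, 9])
  # idempotent on already-canonical input
  d5 <- array(runif(2 * 3 * 4 * 5 * 1), c(2, 3, 4, 5, 1))
  expect_identical(canonicalize_axes(d5, "TZYXC"), d5)
})

test_that("volume invariants are enforced", {
  expect_error(volume_image(array(c(1, NA), c(1, 1, 1, 2, 1))), "non-finite")
  expect_error(volume_image(array(1, c(1, 1, 2, 2, 1)), spacing = c(0, 1, 1)),
               "spacing")
  expect_error(volume_image(array(1, c(2, 2)), axis_order = "ZYX"),
               "names 3 axes")
  expect_error(canonicalize_axes(array(1, c(2, 2)), "YY"), "distinct")
})

test_that("TIFF round trip is exact for integer data and canonical axes", {
  tf <- tempfile(fileext = ".tif")
  # 8-bit integer data round-trips bit-exactly
  m <- matrix(sample(0:255, 64 * 64, replace = TRUE) / 255, 64)
  v <- volume_image(m, axis_order = "YX")
  save_volume(v, tf, bits = 8)
  v2 <- load_volume(tf, "YX")
  expect_identical(v2$data, v$data)
  # multipage z-stack with per-page channels
  a <- array(runif(4 * 16 * 16 * 2), c(4, 16, 16, 2))
  vz <- volume_image(a, axis_order = "ZYXC")
  save_volume(vz, tf, bits = 32)
  v3 <- load_volume(tf, "ZYXC")
  expect_equal(dim(v3$data), dim(vz$data))
  expect_equal(v3$data, vz$data, tolerance = 1e-6)  # float32 precision
})

test_that("page-axis sizes resolve and are validated", {
  tf <- tempfile(fileext = ".tif")
  a <- array(runif(2 * 3 * 8 * 8), c(2, 3, 8, 8, 1))
  save_volume(volume_image(a, spacing = c(2, 1, 1)), tf, bits = 32)
  v <- load_volume(tf, "TZYX", sizes = c(T = 2))
  expect_equal(dim(v$data), c(2, 3, 8, 8, 1))
  expect_equal(v$data[2, 3, , , 1], a[2, 3, , , 1], tolerance = 1e-6)
  expect_error(load_volume(tf, "TZYX", sizes = c(T = 4)), "inconsistent")
  expect_error(load_volume(tf, "TZYX"), "ambiguous")
  expect_error(load_volume(tempfile(), "YX"), "cannot read")
})

test_that("detection CSV round trip reproduces the detection set", {
  d <- detection_set(data.frame(
    t = c(0L, 0L, 1L), z = c(3L, 5L, 2L), y = c(10L, 20L, 30L),
    x = c(7L, 9L, 11L), score = c(0.5, 0.9, 1 / 3)))
  tf <- tempfile(fileext = ".csv")
  save_detections(d, tf)
  d2 <- load_detections(tf)
  expect_equal(d2$records[c("t", "z", "y", "x", "score")],
               d$records[c("t", "z", "y", "x", "score")])
  expect_identical(d2$class_id, d$class_id)
  # rows sorted by t then score descending
  expect_equal(d$records$score[1:2], c(0.9, 0.5))
  # empty set -> header only
  save_detections(detection_set(), tf)
  expect_equal(length(readLines(tf)), 1L)
  expect_equal(nrow(load_detections(tf)$records), 0L)
})

test_that("detection sets reject duplicate voxels", {
  df <- data.frame(t = c(0L, 0L), z = c(1L, 1L), y = c(2L, 2L),
                   x = c(3L, 3L), score = c(0.5, 0.6))
  expect_error(detection_set(df), "duplicate")
})

test_that("annotation serialization round-trips", {
  anns <- list(
    training_annotation("cell", 0, 3, c(5, 5, 40, 60),
                        points = rbind(c(10, 20), c(30, 50.5))),
    training_annotation("cell", 1, 7, c(0, 0, 31, 31)))
  tf <- tempfile(fileext = ".json")
  write_annotations(anns, tf)
  back <- read_annotations(tf)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$points, anns[[1]]$points)
  expect_equal(back[[1]]$region, anns[[1]]$region)
  expect_equal(back[[2]]$z, 7L)
  expect_equal(nrow(back[[2]]$points), 0L)
})

test_that("annotation invariants are enforced", {
  expect_error(training_annotation("c", 0, 0, c(10, 10, 5, 20)), "region")
  expect_error(
    training_annotation("c", 0, 0, c(0, 0, 10, 10), points = rbind(c(15, 5))),
    "inside")
  # empty points list is a valid background annotation
  a <- training_annotation("c", 0, 0, c(0, 0, 10, 10))
  expect_equal(nrow(a$points), 0L)
})

test_that("model round trip preserves predictions and metadata", {
  fx <- small_phantom()
  tf <- tempfile(fileext = ".rds")
  save_model(fx$model, tf)
  m2 <- load_model(tf)
  expect_identical(m2$hyperparams, fx$model$hyperparams)
  expect_identical(m2$kernel_sigma, fx$model$kernel_sigma)
  plane <- centrofind:::vol_plane(normalize_volume(fx$phantom$volume), 0, 10)
  expect_identical(predict_plane(m2, plane), predict_plane(fx$model, plane))
  # corrupted feature metadata is rejected
  bad <- fx$model
  bad$feature_params$scales <- c(1, 2)
  saveRDS(bad, tf)
  expect_error(load_model(tf), "feature specification")
  saveRDS(list(a = 1), tf)
  expect_error(load_model(tf), "not a centrofind model")
})

test_that("percentile normalization maps volumes into [0, 1] per (t, c)", {
  a <- array(rnorm(2 * 4 * 16 * 16 * 1, mean = 100, sd = 10),
             c(2, 4, 16, 16, 1))
  a[1, 1, 1, 1, 1] <- 1e6  # hot pixel
  v <- normalize_volume(volume_image(a))
  expect_gte(min(v$data), 0)
  expect_lte(max(v$data), 1)
  # the hot pixel is clipped, not allowed to compress the rest
  expect_gt(median(v$data[1, , , , 1]), 0.2)
})
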