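square <- function(half, cy = 50, cx = 50) {
  rbind(c(cy - half, cx - half), c(cy - half, cx + half),
        c(cy + half, cx + half), c(cy + half, cx - half))
}

test_that("interpolation between identical keyframes is constant", {
  roi <- polygon_roi(list(list(t = 0, z = 0, vertices = square(10)),
                          list(t = 0, z = 10, vertices = square(10))))
  p5 <- interpolate_roi(roi, 0, 5)
  expect_equal(max(p5[, 1]), 60); expect_equal(min(p5[, 1]), 40)
  expect_equal(max(p5[, 2]), 60); expect_equal(min(p5[, 2]), 40)
})

test_that("interpolated polygons have intermediate size (Monte-Carlo area)", {
  roi <- polygon_roi(list(list(t = 0, z = 0, vertices = square(10)),
                          list(t = 0, z = 10, vertices = square(20))))
  p5 <- interpolate_roi(roi, 0, 5)
  set.seed(1)
  pts <- cbind(runif(20000, 0, 100), runif(20000, 0, 100))
  area <- mean(point_in_polygon(pts, p5)) * 100 * 100
  expect_equal(area, 30^2, tolerance = 0.05)
})

test_that("queries outside the keyframe range clamp to the nearest keyframe", {
  roi <- polygon_roi(list(list(t = 0, z = 2, vertices = square(10)),
                          list(t = 0, z = 8, vertices = square(20))))
  expect_equal(interpolate_roi(roi, 0, 100), interpolate_roi(roi, 0, 8))
  expect_equal(interpolate_roi(roi, 0, 0), interpolate_roi(roi, 0, 2))
  expect_equal(interpolate_roi(roi, 5, 8), interpolate_roi(roi, 0, 8))
})

test_that("interpolation at a keyframe reproduces the resampled keyframe", {
  tri <- rbind(c(10, 10), c(10, 40), c(35, 25))
  roi <- polygon_roi(list(list(t = 0, z = 0, vertices = tri),
                          list(t = 0, z = 6, vertices = square(10))))
  expect_equal(interpolate_roi(roi, 0, 0), resample_polygon(tri, 100))
})

test_that("interpolation varies continuously between keyframes", {
  roi <- polygon_roi(list(list(t = 0, z = 0, vertices = square(10)),
                          list(t = 0, z = 10, vertices = square(20,
                                                                cy = 60))))
  total <- max(abs(interpolate_roi(roi, 0, 10) - interpolate_roi(roi, 0, 0)))
  for (z in 0:9) {
    step <- max(abs(interpolate_roi(roi, 0, z + 1) -
                    interpolate_roi(roi, 0, z)))
    expect_lte(step, total / 10 + 1e-9)
  }
})

test_that("point-in-polygon matches the convex half-plane oracle", {
  set.seed(4)
  # random convex polygon (hull of random points)
  raw <- cbind(runif(12, 10, 90), runif(12, 10, 90))
  hull <- raw[rev(grDevices::chull(raw[, 2], raw[, 1])), ]
  pts <- cbind(runif(500, 0, 100), runif(500, 0, 100))
  got <- point_in_polygon(pts, hull)
  # oracle: inside iff on the same side of every directed hull edge
  n <- nrow(hull)
  oracle <- rep(TRUE, nrow(pts))
  for (k in seq_len(n)) {
    a <- hull[k, ]; b <- hull[k %% n + 1, ]
    cross <- (b[2] - a[2]) * (pts[, 1] - a[1]) -
             (b[1] - a[1]) * (pts[, 2] - a[2])
    side <- (b[2] - a[2]) * (mean(hull[, 1]) - a[1]) -
            (b[1] - a[1]) * (mean(hull[, 2]) - a[2])
    oracle <- oracle & (cross * sign(side) >= -1e-9)
  }
  expect_equal(got, oracle)
  # boundary points count as inside
  sq <- square(10)
  expect_true(all(point_in_polygon(rbind(c(40, 50), c(60, 60)), sq)))
})

test_that("ROI filtering keeps inside detections and drops outside ones", {
  d <- detection_set(data.frame(t = 0L, z = c(0L, 0L), y = c(50L, 5L),
                                x = c(50L, 5L), score = c(0.9, 0.8)))
  roi <- polygon_roi(list(list(t = 0, z = 0, vertices = square(10))))
  kept <- filter_detections(d, roi)
  expect_equal(nrow(kept$records), 1L)
  expect_equal(kept$records$y, 50L)
  far <- polygon_roi(list(list(t = 0, z = 0,
                               vertices = square(2, cy = 90, cx = 90))))
  expect_equal(nrow(filter_detections(d, far)$records), 0L)
})

test_that("ROI serialization round-trips", {
  roi <- polygon_roi(list(list(t = 0, z = 0, vertices = square(10)),
                          list(t = 3, z = 8, vertices = square(15))),
                     n_points = 64)
  tf <- tempfile(fileext = ".json")
  write_roi(roi, tf)
  back <- read_roi(tf)
  expect_equal(back$n_points, 64L)
  expect_equal(interpolate_roi(back, 1, 4), interpolate_roi(roi, 1, 4))
})

test_that("degenerate polygons are rejected", {
  expect_error(polygon_roi(list(list(t = 0, z = 0,
                                     vertices = rbind(c(0, 0), c(1, 1))))),
               ">= 3")
  expect_error(polygon_roi(list(list(t = 0, z = 0, vertices = square(5)),
                                list(t = 0, z = 0, vertices = square(7)))),
               "one keyframe")
})
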