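test_that("the packaged calibration grid has the published layout", {
  g <- table1_grid()
  expect_equal(g$velocities, c(100, 150, 400, 1000))
  expect_equal(g$depths, c(2, 2.1, 2.2, 2.3, 2.4, 3))
  expect_equal(dim(g$volumes), c(4L, 6L))
})

test_that("prediction is exact at every grid node", {
  g <- table1_grid()
  for (i in seq_along(g$velocities)) {
    for (j in seq_along(g$depths)) {
      expect_identical(predict_volume(g, g$velocities[i], g$depths[j]),
                       g$volumes[i, j])
    }
  }
})

test_that("volume increases with velocity where the published grid does", {
  g <- table1_grid()
  # strictly monotone in v at depths 2-2.3 mm; the printed 2.4 and 3 mm
  # columns each dip once at 150 mm/s and are reproduced as printed
  for (j in 1:4) {
    expect_true(all(diff(g$volumes[, j]) > 0))
  }
  for (j in 5:6) {
    expect_identical(unname(which(diff(g$volumes[, j]) < 0)), 1L)
  }
  # the bilinear interpolant inherits monotonicity between monotone nodes
  for (d in c(2, 2.15, 2.3)) {
    v <- vapply(seq(100, 1000, by = 50),
                function(x) predict_volume(g, x, d), 1)
    expect_true(all(diff(v) >= 0))
  }
})

test_that("bilinear interpolation matches hand arithmetic", {
  g <- table1_grid()
  expect_equal(predict_volume(g, 125, 2), (13.27 + 13.53) / 2,
               tolerance = 1e-12)
  # generic point against the textbook bilinear formula
  v <- 200; h <- 2.35
  t_v <- (v - 150) / (400 - 150); t_h <- (h - 2.3) / (2.4 - 2.3)
  ref <- (1 - t_v) * ((1 - t_h) * 25.00 + t_h * 31.26) +
    t_v * ((1 - t_h) * 27.31 + t_h * 32.27)
  expect_equal(predict_volume(g, v, h), ref, tolerance = 1e-12)
})

test_that("queries outside the envelope are clamped with a warning", {
  g <- table1_grid()
  expect_warning(v <- predict_volume(g, 50, 1.5), "envelope")
  expect_identical(v, 13.27)
})

test_that("CSV loading validates structure", {
  one_row <- tempfile(fileext = ".csv")
  writeLines(c("velocity_mm_s,depth_2,depth_3", "100,10,20"), one_row)
  g <- load_calibration(one_row)
  expect_equal(g$velocities, 100)
  expect_equal(g$volumes[1, ], c(`2` = 10, `3` = 20))

  dup <- tempfile(fileext = ".csv")
  writeLines(c("velocity_mm_s,depth_2", "100,10", "100,11"), dup)
  expect_error(load_calibration(dup), "duplicated velocity")

  ragged <- tempfile(fileext = ".csv")
  writeLines(c("velocity_mm_s,depth_2,depth_3", "100,10,", "150,11,12"),
             ragged)
  expect_error(load_calibration(ragged), "missing cells")

  bad <- tempfile(fileext = ".csv")
  writeLines(c("velocity_mm_s,deep_2", "100,10"), bad)
  expect_error(load_calibration(bad), "unexpected column")
})

test_that("depth inversion recovers grid nodes and interior targets", {
  g <- table1_grid()
  expect_equal(invert_for_depth(g, 100, 61.72), 3, tolerance = 1e-12)
  # interior target: cross-check with a bisection oracle on the interpolant
  target <- (31.42 + 61.72) / 2
  h <- invert_for_depth(g, 100, target)
  oracle <- stats::uniroot(function(x) predict_volume(g, 100, x) - target,
                           c(2.4, 3), tol = 1e-9)$root
  expect_equal(h, oracle, tolerance = 1e-3)
  expect_lt(abs(predict_volume(g, 100, h) - target), 0.01)
})

test_that("inversion then prediction is the identity on the monotone region", {
  g <- table1_grid()
  for (h in seq(2.0, 3.0, by = 0.13)) {
    vol <- predict_volume(g, 100, h)
    expect_equal(invert_for_depth(g, 100, vol), h, tolerance = 1e-3)
  }
})

test_that("unreachable targets report the achievable range", {
  g <- table1_grid()
  err <- tryCatch(invert_for_depth(g, 100, 5), condition = identity)
  expect_s3_class(err, "pindrop_range_error")
  expect_equal(err$achievable_nl, c(13.27, 61.72))
  expect_error(invert_for_depth(g, 100, 100), "unreachable")
})

test_that("non-monotone depth profiles return the smallest solving depth", {
  # at 400 mm/s the profile dips at 2.2 mm (25.89 -> 20.45 -> 27.31)
  g <- table1_grid()
  h <- invert_for_depth(g, 400, 23)
  expect_lt(h, 2.2)
  expect_lt(abs(predict_volume(g, 400, h) - 23), 0.01)
})

test_that("linear depth extension preserves the original nodes", {
  g <- table1_grid()
  eg <- extend_calibration(g, 5)
  expect_identical(eg$volumes[, seq_along(g$depths)], g$volumes)
  # appended nodes continue the last segment's slope
  slope <- (g$volumes[, 6] - g$volumes[, 5]) / (3 - 2.4)
  expect_equal(eg$volumes[, 7], g$volumes[, 6] + 0.5 * slope,
               tolerance = 1e-12)
  expect_identical(extend_calibration(g, 2.5), g)
})

test_that("grid constructor enforces its invariants", {
  expect_error(calibration_grid(c(2, 1), 1, matrix(1, 2, 1)),
               "strictly increasing")
  expect_error(calibration_grid(1, c(1, 1.5), matrix(c(1, NA), 1, 2)),
               "missing")
  expect_error(calibration_grid(1, 1, matrix(-1, 1, 1)), "positive")
})
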