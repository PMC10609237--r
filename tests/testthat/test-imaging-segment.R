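test_that("binarize splits dark and bright foreground as complements", {
  img <- gray_image(matrix(c(10L, 200L, 200L, 10L), 2, 2))
  dark <- binarize(img, 50, "dark_foreground")
  bright <- binarize(img, 50, "bright_foreground")
  expect_identical(strip_img(dark), strip_img(img) <= 50L)
  expect_identical(strip_img(bright), !strip_img(dark))
})

test_that("foreground and background always partition the image", {
  set.seed(44)
  img <- random_gray(16, 16)
  for (k in c(1L, 128L, 255L)) {
    fg <- unclass(binarize(img, k, "dark_foreground"))
    bg <- unclass(binarize(img, k, "bright_foreground"))
    expect_true(all(xor(fg, bg)))
  }
  expect_error(binarize(img, 0), "threshold")
  expect_error(binarize(img, 256), "threshold")
})

test_that("a filled square yields one outer contour of its boundary", {
  m <- matrix(FALSE, 10, 10)
  m[4:7, 4:7] <- TRUE
  cts <- trace_contours(as_binary(m))
  expect_length(cts, 1)
  expect_identical(cts[[1]]$kind, "outer")
  boundary <- m
  boundary[5:6, 5:6] <- FALSE  # interior of the 4x4 square
  expect_identical(coord_key(unique(cts[[1]]$coords)), mask_key(boundary))
  expect_identical(nrow(unique(cts[[1]]$coords)), 12L)
})

test_that("empty foreground yields no contours and an area error", {
  m <- matrix(FALSE, 6, 6)
  expect_identical(trace_contours(as_binary(m)), list())
  expect_error(measure_area(as_binary(m)), "no droplet")
})

test_that("a ring yields an outer and an inner contour", {
  m <- matrix(FALSE, 8, 8)
  m[3:6, 3:6] <- TRUE
  m[4:5, 4:5] <- FALSE  # 2x2 hole
  cts <- trace_contours(as_binary(m))
  kinds <- vapply(cts, function(x) x$kind, "")
  expect_identical(sort(kinds), c("inner", "outer"))
  # every ring pixel touches both the outside and the hole
  ring <- mask_key(m)
  outer <- cts[kinds == "outer"][[1]]
  inner <- cts[kinds == "inner"][[1]]
  expect_identical(coord_key(unique(outer$coords)), ring)
  expect_identical(coord_key(unique(inner$coords)), ring)
})

test_that("contours are closed 8-connected walks covering the exact boundary", {
  set.seed(55)
  for (rep in 1:8) {
    m <- random_blob_mask()
    cts <- trace_contours(as_binary(m))
    if (!any(m)) next
    for (ct in cts) {
      q <- ct$coords
      if (nrow(q) > 1) {
        steps <- rbind(diff(q), q[1, ] - q[nrow(q), ])  # includes closure
        expect_true(all(abs(steps) <= 1 & rowSums(abs(steps)) >= 1))
      }
    }
    lab <- pindrop:::label_components_cpp(m, 8L)
    outside <- pindrop:::outside_background_cpp(m)
    holes <- !m & !outside
    outer_ref <- oracle_boundary(m, outside, include_oob = TRUE)
    inner_ref <- oracle_boundary(m, holes, include_oob = FALSE)
    got_outer <- do.call(rbind, lapply(cts[vapply(cts, `[[`, "", "kind") ==
                                             "outer"], `[[`, "coords"))
    expect_identical(coord_key(unique(got_outer)), mask_key(outer_ref))
    inner_cts <- cts[vapply(cts, `[[`, "", "kind") == "inner"]
    if (length(inner_cts) || any(inner_ref)) {
      got_inner <- do.call(rbind, lapply(inner_cts, `[[`, "coords"))
      expect_identical(coord_key(unique(got_inner)), mask_key(inner_ref))
    }
  }
})

test_that("area counts the largest component with holes filled", {
  full <- matrix(TRUE, 10, 10)
  expect_identical(as.integer(measure_area(as_binary(full))), 100L)

  two <- matrix(FALSE, 20, 20)
  two[2:11, 2:6] <- TRUE            # 50 px
  two[15:17, 15:17] <- TRUE; two[15, 17] <- FALSE; two[17, 15] <- FALSE  # 7 px
  a <- measure_area(as_binary(two))
  expect_identical(as.integer(a), 50L)
  expect_identical(attr(a, "n_components"), 2L)
  expect_identical(attr(a, "component_areas"), c(50L, 7L))

  ring <- matrix(FALSE, 8, 8)
  ring[3:6, 3:6] <- TRUE
  ring[4:5, 4:5] <- FALSE
  expect_identical(as.integer(measure_area(as_binary(ring))), 16L)
})

test_that("rasterized disk areas match brute-force counts and stay in the rim band", {
  for (rad in c(20, 50, 71, 100)) {
    n <- 2L * rad + 9L
    ctr <- (n + 1) / 2
    r <- matrix(seq_len(n), n, n); c <- t(r)
    m <- sqrt((r - ctr)^2 + (c - ctr)^2) <= rad  # centre-inclusion rule
    a <- as.integer(measure_area(as_binary(m)))
    expect_identical(a, sum(m))
    expect_lte(abs(a - pi * rad^2), 2 * pi * rad + 8)
  }
})
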