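test_that("grayscale conversion uses BT.601 weights with half-up rounding", {
  v <- array(0, c(2, 2, 3))
  v[, , 1] <- 200; v[, , 2] <- 200; v[, , 3] <- 200
  expect_equal(to_grayscale(v), matrix(200, 2, 2))

  red <- array(0, c(1, 1, 3)); red[1, 1, 1] <- 255
  expect_equal(as.vector(to_grayscale(red)), 76)  # 0.299 * 255 = 76.245

  black <- array(0, c(3, 3, 3))
  expect_equal(to_grayscale(black), matrix(0, 3, 3))
  # 1-channel passes through
  m <- matrix(7, 4, 4)
  expect_identical(to_grayscale(m), m)
})

test_that("gaussian smoothing preserves constants and matches direct convolution", {
  const <- matrix(123, 10, 10)
  expect_equal(gaussian_smooth(const, 5), const)

  k <- contourtl:::gaussian_kernel(5, 1.1)
  expect_equal(sum(k), 1, tolerance = 1e-9)

  # centered unit impulse: symmetric response, max at center, equals the
  # direct convolution oracle after quantization
  imp <- matrix(0, 9, 9); imp[5, 5] <- 255
  sm <- gaussian_smooth(imp, 5, sigma = 1.1)
  expect_equal(which(sm == max(sm)), 5 + 4 * 9)
  expect_equal(sm, sm[9:1, ])            # vertical symmetry
  expect_equal(sm, sm[, 9:1])            # horizontal symmetry
  oracle <- pmin(pmax(floor(convolve_direct(imp, k) + 0.5), 0), 255)
  expect_equal(sm, oracle)

  expect_error(gaussian_smooth(const, 4), "odd")
})

test_that("binarize follows the strict-threshold rule and is monotone in T", {
  img <- matrix(c(44, 45, 0, 255), 2, 2)
  b <- binarize(img, 45)
  expect_equal(as.vector(b), c(0, 255, 0, 255))
  expect_true(all(b %in% c(0, 255)))

  expect_equal(binarize(matrix(0, 4, 4), 1), matrix(0, 4, 4))

  half <- cbind(matrix(0, 8, 4), matrix(255, 8, 4))
  expect_equal(sum(binarize(half, 128) == 255), 32)

  # raising T never adds foreground
  set.seed(3)
  img <- matrix(sample(0:255, 100, TRUE), 10, 10)
  for (t in c(10, 60, 120, 200)) {
    expect_true(all(binarize(img, t + 30) <= binarize(img, t)))
  }
})

test_that("morphological opening removes specks and restores solid squares", {
  speck <- matrix(0, 9, 9); speck[5, 5] <- 255
  expect_equal(sum(morph_clean(speck, morph_params(3, 1, 0))), 0)

  sq <- matrix(0, 30, 30); sq[6:25, 6:25] <- 255
  expect_equal(morph_clean(sq, morph_params(3, 2, 2)), sq)

  empty <- matrix(0, 12, 12)
  expect_equal(morph_clean(empty), empty)

  # identity at zero iterations; erosion shrinks, dilation grows
  expect_equal(morph_clean(sq, morph_params(3, 0, 0)), sq)
  er <- morph_clean(sq, morph_params(3, 1, 0))
  di <- morph_clean(sq, morph_params(3, 0, 1))
  expect_true(all(er <= sq) && sum(er) < sum(sq))
  expect_true(all(di >= sq) && sum(di) > sum(sq))
})

test_that("external contour retrieval matches component structure", {
  sq <- matrix(0, 20, 20); sq[6:15, 6:15] <- 255
  cs <- find_external_contours(sq)
  expect_length(cs, 1)
  expect_equal(cs[[1]]$area, 100)

  # ring: the interior hole is not reported
  ring <- matrix(0, 20, 20); ring[4:16, 4:16] <- 255; ring[8:12, 8:12] <- 0
  expect_length(find_external_contours(ring), 1)

  expect_identical(find_external_contours(matrix(0, 5, 5)), list())

  # contour count equals the flood-fill component count on random masks
  for (s in 1:8) {
    m <- random_mask(s, 24 + s, 30, p = 0.25)
    m <- morph_clean(m, morph_params(3, 0, 0))  # no-op, keeps {0,255}
    expect_equal(length(find_external_contours(m)), flood_fill_components(m),
                 info = paste("mask seed", s))
  }
})

test_that("contour boundaries stay within their component's pixel extent", {
  for (s in 1:5) {
    m <- random_mask(s + 100, 32, 32, p = 0.35)
    cs <- find_external_contours(m)
    for (ct in cs) {
      expect_true(all(ct$points[, 1] >= 1 & ct$points[, 1] <= 32))
      expect_true(all(m[ct$points] == 255))  # boundary points are foreground
    }
  }
})

test_that("largest contour selection is by filled area with exact bbox", {
  m <- matrix(0, 60, 60)
  m[10:19, 30:39] <- 255   # area 100
  m[40:44, 5:9] <- 255     # area 25
  cs <- find_external_contours(m)
  bb <- largest_contour_bbox(cs)
  expect_equal(bb, list(row_min = 10, col_min = 30, row_max = 19, col_max = 39))

  one <- matrix(0, 60, 60); one[11:21, 31:51] <- 255
  bb1 <- largest_contour_bbox(find_external_contours(one))
  expect_equal(unlist(bb1), c(row_min = 11, col_min = 31, row_max = 21, col_max = 51))

  expect_error(largest_contour_bbox(list()), class = "contourtl_no_contour")
})

test_that("crop respects inclusive-extent arithmetic", {
  img <- matrix(seq_len(56 * 64) %% 256, 56, 64)
  full <- crop_image(img, list(row_min = 1, col_min = 1, row_max = 56, col_max = 64))
  expect_identical(full, img)

  px <- crop_image(img, list(row_min = 1, col_min = 1, row_max = 1, col_max = 1))
  expect_equal(dim(px), c(1, 1))
  expect_equal(px[1, 1], img[1, 1])

  sub <- crop_image(img, list(row_min = 11, col_min = 31, row_max = 21, col_max = 51))
  expect_equal(dim(sub), c(11, 21))
  expect_identical(sub, img[11:21, 31:51])

  expect_error(crop_image(img, list(row_min = 0, col_min = 1, row_max = 5, col_max = 5)),
               "bounds")
})

test_that("extract_brain tightly bounds the phantom's ellipse", {
  ph <- small_phantom(7, tumor = TRUE)
  crop <- extract_brain(ph$image)
  expect_lte(length(crop), length(ph$image))
  # the crop must cover at least the brain's true pixel extent
  brain <- ph$image > 60
  rows <- range(which(rowSums(brain) > 0)); cols <- range(which(colSums(brain) > 0))
  box <- attr(crop, "bbox")
  expect_lte(box$row_min, rows[1] + 2); expect_gte(box$row_max, rows[2] - 2)
  expect_lte(box$col_min, cols[1] + 2); expect_gte(box$col_max, cols[2] - 2)
  expect_lte(nrow(crop) * ncol(crop), length(ph$image))

  # near-idempotence: re-extracting an extracted brain barely moves the box
  crop2 <- extract_brain(crop)
  expect_lte(abs(nrow(crop2) - nrow(crop)), 4)
  expect_lte(abs(ncol(crop2) - ncol(crop)), 4)

  expect_error(extract_brain(matrix(0, 50, 50)),
               class = "contourtl_no_contour")
})
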