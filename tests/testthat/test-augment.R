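test_that("rotations behave like the rotation group", {
  img <- matrix(sample(0:255, 40 * 40, TRUE), 40, 40)
  expect_identical(rotate_image(img, 0), img)

  r <- img
  for (i in 1:4) r <- rotate_image(r, 90)
  expect_identical(r, img)

  # right-angle rotations are exact pixel permutations
  expect_equal(sort(as.vector(rotate_image(img, 90))), sort(as.vector(img)))
  expect_identical(rotate_image(rotate_image(img, 90), 270), img)
  expect_identical(rotate_image(img, 180),
                   flip_image(flip_image(img, "horizontal"), "vertical"))

  # R(theta) algebra: orthonormal columns, determinant 1
  for (theta in c(15, 45, 123)) {
    a <- theta * pi / 180
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    expect_equal(t(R) %*% R, diag(2), tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }

  # non-right angles preserve shape and range
  r15 <- rotate_image(img, 15)
  expect_equal(dim(r15), dim(img))
  expect_true(all(r15 >= 0 & r15 <= 255))
})

test_that("flips are involutions that reverse the stated axis", {
  img <- matrix(sample(0:255, 30 * 20, TRUE), 30, 20)
  expect_identical(flip_image(flip_image(img, "vertical"), "vertical"), img)
  expect_identical(flip_image(flip_image(img, "horizontal"), "horizontal"), img)

  row3 <- matrix(c(1, 2, 3), 1, 3)
  expect_equal(as.vector(flip_image(row3, "horizontal")), c(3, 2, 1))
  expect_equal(flip_image(img, "vertical"), img[30:1, ])
})

test_that("zoom preserves shape and constants", {
  img <- matrix(sample(0:255, 48 * 48, TRUE), 48, 48)
  expect_identical(zoom_image(img, 1), img)
  for (f in c(1.25, 0.8, 2)) {
    expect_equal(dim(zoom_image(img, f)), dim(img))
  }
  const <- matrix(144, 40, 40)
  expect_equal(zoom_image(const, 1.25), const)
  expect_error(zoom_image(img, 100), "too large")
  expect_error(zoom_image(img, 0), "factor")
})

test_that("standard plans have the exact cardinality, identity first, distinct ops", {
  for (k in c(8, 36)) {
    plan <- standard_plan(k)
    expect_length(plan$ops, k)
    expect_equal(plan$ops[[1]]$name, "identity")
    sigs <- vapply(plan$ops, function(o)
      paste(o$theta, o$flip, o$factor), character(1))
    expect_equal(anyDuplicated(sigs), 0)
  }
  expect_error(standard_plan(12), "8 and 36")
})

test_that("plan application multiplies the manifest exactly and keeps labels", {
  d <- withr::local_tempdir()
  manifest <- generate_phantom_dataset(3, 2, file.path(d, "src"), seed = 4,
                                       spec_ranges = test_ranges())
  out <- apply_plan(manifest, standard_plan(8), file.path(d, "aug"))
  expect_equal(nrow(out), 5 * 8)
  expect_true(all(file.exists(out$path)))
  # labels inherited from the source image
  expect_equal(out$label, rep(manifest$label, each = 8))
  expect_equal(out$source, rep(manifest$path, each = 8))

  # identity-only plan keeps the label multiset
  id_plan <- structure(list(ops = list(augment_op()), name = "x1"),
                       class = "augmentation_plan")
  out1 <- apply_plan(manifest, id_plan, file.path(d, "id"))
  expect_equal(sort(out1$label), sort(manifest$label))
  # identity op writes an unchanged image
  expect_identical(read_image(out1$path[1]), read_image(manifest$path[1]))

  # shape and intensity-multiset preservation for permutation ops on squares
  img <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  for (op in standard_plan(8)$ops) {
    res <- apply_op(img, op)
    expect_equal(dim(res), dim(img), info = op$name)
    if (op$name %in% c("identity", "rot90", "rot180", "rot270",
                       "flip_h", "flip_v")) {
      expect_equal(sort(as.vector(res)), sort(as.vector(img)), info = op$name)
    }
  }
})
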