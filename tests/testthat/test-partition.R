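fake_manifest <- function(n, n_pos = round(n / 2), source = NULL) {
  m <- data.frame(path = sprintf("img_%05d.png", seq_len(n)),
                  label = c(rep(1L, n_pos), rep(0L, n - n_pos)),
                  stringsAsFactors = FALSE)
  if (!is.null(source)) m$source <- source
  m
}

test_that("partition sizes follow the ceiling-rounding scheme", {
  expect_equal(partition_sizes(3000, split_spec(0.2, 0.2)),
               c(train = 1920L, val = 480L, test = 600L))
  expect_equal(partition_sizes(24000, split_spec(0, 0.3)),
               c(train = 16800L, val = 7200L, test = 0L))
  expect_equal(partition_sizes(9108, split_spec(0.2, 0.2)),
               c(train = 5828L, val = 1458L, test = 1822L))
  expect_equal(partition_sizes(10, split_spec(0.2, 0.2)),
               c(train = 6L, val = 2L, test = 2L))
  expect_error(split_spec(1.2, 0.2), "fractions")
})

test_that("row-level splits hit exact sizes, conserve rows, and stratify", {
  m <- fake_manifest(9108, n_pos = 5580)
  sp <- split_spec(0.2, 0.2, group_by_source = FALSE, seed = 7)
  p <- split_dataset(m, sp)
  expect_equal(nrow(p$train), 5828)
  expect_equal(nrow(p$validation), 1458)
  expect_equal(nrow(p$test), 1822)

  all_rows <- rbind(p$train, p$validation, p$test)
  expect_setequal(all_rows$path, m$path)
  expect_equal(nrow(all_rows), nrow(m))

  # stratification: per-class proportions within one item of the overall rate
  for (part in p[c("train", "validation", "test")]) {
    expect_lte(abs(sum(part$label == 1) - 5580 / 9108 * nrow(part)), 1.5)
  }

  # determinism under seed; different seeds differ
  p2 <- split_dataset(m, sp)
  expect_identical(p, p2)
  p3 <- split_dataset(m, split_spec(0.2, 0.2, group_by_source = FALSE, seed = 8))
  expect_false(identical(p$test$path, p3$test$path))

  expect_error(split_dataset(m[0, ], sp), "empty")
})

test_that("source-grouped splits never separate augmented variants", {
  src <- rep(sprintf("src_%03d.png", 1:40), each = 6)
  m <- fake_manifest(240, n_pos = 120, source = src)
  m$label <- rep(rep(c(1L, 0L), each = 20), each = 6)
  p <- split_dataset(m, split_spec(0.2, 0.2, group_by_source = TRUE, seed = 1))
  for (part_name in c("train", "validation", "test")) {
    others <- setdiff(c("train", "validation", "test"), part_name)
    for (o in others) {
      expect_length(intersect(p[[part_name]]$source, p[[o]]$source), 0)
    }
  }
  expect_equal(nrow(p$train) + nrow(p$validation) + nrow(p$test), 240)
  # grouped sizes are within one group of the row-level target
  expect_lte(abs(nrow(p$test) - 48), 6)
})

test_that("the unseen scenario takes the whole test manifest and guards leakage", {
  train_m <- fake_manifest(200, n_pos = 100)
  test_m <- data.frame(path = sprintf("unseen_%04d.png", 1:60),
                       label = rep(c(1L, 0L), each = 30),
                       stringsAsFactors = FALSE)
  p <- build_unseen_scenario(train_m, test_m)
  expect_equal(nrow(p$train), 140)       # 70% of 200
  expect_equal(nrow(p$validation), 60)   # 30% of 200
  expect_equal(nrow(p$test), 60)
  expect_setequal(p$test$path, test_m$path)

  leaky <- test_m
  leaky$path[1] <- train_m$path[1]
  expect_error(build_unseen_scenario(train_m, leaky),
               class = "contourtl_leakage")

  # leakage through shared augmentation sources is also caught
  aug_train <- train_m; aug_train$source <- paste0("orig_", seq_len(200))
  aug_test <- test_m; aug_test$source <- c("orig_5", paste0("other_", 2:60))
  expect_error(build_unseen_scenario(aug_train, aug_test),
               class = "contourtl_leakage")

  empty_test <- test_m[0, ]
  p0 <- build_unseen_scenario(train_m, empty_test)
  expect_equal(nrow(p0$test), 0)
  expect_equal(nrow(p0$train) + nrow(p0$validation), 200)
})
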