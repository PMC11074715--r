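# Model tests run on reduced-width networks (identical topology, scaled
# filter counts) so the suite stays CPU-friendly; the full-width census is
# exercised in the acceptance suite.

reduced_spec <- function(...) {
  model_spec(width_multiplier = 1 / 16, head_widths = c(32, 16, 8),
             dropout_rate = 0.3, ...)
}

test_that("softmax and relu follow their closed forms", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax(c(log(1), log(3))), c(0.25, 0.75))
  big <- softmax(c(1000, 0))
  expect_true(all(is.finite(big)))
  expect_equal(big[1], 1, tolerance = 1e-12)
  expect_equal(sum(softmax(rnorm(5))), 1, tolerance = 1e-12)

  expect_equal(relu(-2), 0)
  expect_equal(relu(3), 3)
  expect_equal(relu(0), 0)
  # compositions stay non-negative and finite
  z <- softmax(relu(c(-5, 0.3, 2)))
  expect_true(all(z >= 0) && all(is.finite(z)))
})

test_that("the built architecture satisfies the layer census", {
  net <- build_contourtl_net(reduced_spec(), seed = 1)
  convs <- Filter(function(l) l$type == "conv", net$layers)
  expect_length(convs, 13)
  expect_true(all(vapply(convs, function(l) all(l$kernel == c(3, 3)), logical(1))))
  expect_true(all(vapply(convs, function(l) l$stride == 1, logical(1))))
  expect_equal(sum(!vapply(convs, `[[`, logical(1), "trainable")), 10)
  expect_false(any(vapply(convs[1:10], `[[`, logical(1), "trainable")))

  pools <- Filter(function(l) l$type == "pool", net$layers)
  expect_length(pools, 5)
  expect_true(all(vapply(pools, function(l) all(l$window == c(2, 2)) &&
                           l$stride == 2, logical(1))))

  # spatial halving 144 -> 72 -> 36 -> 18 -> 9 -> 4
  flat <- Filter(function(l) l$type == "flatten", net$layers)[[1]]
  expect_equal(flat$feature_dim[1:2], c(4, 4))

  denses <- Filter(function(l) l$type == "dense", net$layers)
  drops <- Filter(function(l) l$type == "dropout", net$layers)
  expect_length(denses, 4)  # 3 hidden + softmax output
  expect_length(drops, 3)
  expect_equal(denses[[4]]$activation, "softmax")
  expect_equal(nrow(denses[[4]]$W), 2)

  expect_error(model_spec(frozen_conv = 10, trainable_conv = 5), "equal 13")
  expect_error(model_spec(dropout_rate = 1), "dropout_rate")
})

test_that("prediction yields probability pairs, deterministically", {
  net <- build_contourtl_net(reduced_spec(), seed = 2)
  imgs <- lapply(1:3, function(s) {
    set.seed(s); matrix(sample(0:255, 144 * 144, TRUE), 144, 144)
  })
  p <- predict(net, imgs)
  expect_equal(dim(p), c(3, 2))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  expect_identical(predict(net, imgs), p)
  cls <- predict(net, imgs, type = "class")
  expect_equal(cls, max.col(p) - 1L)

  expect_error(predict(net, matrix(0, 100, 100)), "expects 144x144")
})

test_that("seeded builds are reproducible and weight round trips are exact", {
  a <- build_contourtl_net(reduced_spec(), seed = 9)
  b <- build_contourtl_net(reduced_spec(), seed = 9)
  expect_identical(save_weights(a), save_weights(b))
  c2 <- build_contourtl_net(reduced_spec(), seed = 10)
  expect_false(identical(save_weights(a), save_weights(c2)))

  rebuilt <- build_contourtl_net(reduced_spec(), seed = 10,
                                 weights = save_weights(a))
  expect_identical(save_weights(rebuilt), save_weights(a))
})

test_that("early stopping obeys its patience contract", {
  net <- build_contourtl_net(reduced_spec(), seed = 4)
  set.seed(11)
  imgs <- lapply(1:6, function(i) matrix(sample(0:255, 144 * 144, TRUE), 144, 144))
  dat <- list(train = list(images = imgs[1:4], labels = c(0L, 1L, 0L, 1L)),
              validation = list(images = imgs[5:6], labels = c(0L, 1L)))
  # zero learning rate freezes the loss: patience 1 stops at epoch 2
  fit <- train_model(net, dat, train_config(learning_rate = 0, max_epochs = 10,
                                            batch_size = 2, patience = 1,
                                            seed = 1))
  expect_equal(fit$history$stopped_epoch, 2)
  expect_equal(nrow(fit$history$epochs), 2)
  expect_lte(nrow(fit$history$epochs), 10)
  # zero learning rate must leave every weight untouched
  expect_identical(save_weights(fit), save_weights(net))
})

test_that("a small random-init run learns separable phantoms", {
  build_set <- function(seeds, tumor) {
    lapply(seeds, function(s) small_segmented(s, tumor, noise_sd = 0,
                                              threshold = 150))
  }
  accs <- vapply(1:3, function(seed) {
    tr <- list(images = c(build_set(1:12 + 100 * seed, TRUE),
                          build_set(1:12 + 100 * seed + 50, FALSE)),
               labels = rep(c(1L, 0L), each = 12))
    va <- list(images = c(build_set(97:99 + 1000 * seed, TRUE),
                          build_set(77:79 + 1000 * seed, FALSE)),
               labels = rep(c(1L, 0L), each = 3))
    net <- build_contourtl_net(reduced_spec(), seed = seed)
    fit <- train_model(net, list(train = tr, validation = va),
                       train_config(learning_rate = 1e-3, max_epochs = 15,
                                    batch_size = 8, patience = 15, seed = seed))
    utils::tail(fit$history$epochs$acc, 1)
  }, numeric(1))
  expect_gte(sum(accs >= 0.9), 2)
})

test_that("analytic gradients match central finite differences", {
  spec <- model_spec(input_side = 32, frozen_conv = 0, trainable_conv = 13,
                     head_widths = c(8, 6, 4), dropout_rate = 0,
                     width_multiplier = 1 / 32)
  net <- build_contourtl_net(spec, seed = 3)
  set.seed(9)
  x <- contourtl:::prep_input(net, matrix(sample(0:255, 32 * 32, TRUE), 32, 32))
  fw <- contourtl:::forward_layers(net, x, train = TRUE)
  y <- 1L
  dz <- fw$out; dz[y + 1] <- dz[y + 1] - 1
  g <- contourtl:::backward_layers(net, dz, fw$caches, to = 1L)
  loss_at <- function(m) -log(contourtl:::forward_layers(m, x)$out[y + 1])
  eps <- 1e-6
  param_layers <- which(vapply(net$layers, function(l)
    l$type %in% c("conv", "dense"), logical(1)))
  for (li in param_layers[c(1, 4, 11, length(param_layers))]) {
    wf <- if (net$layers[[li]]$type == "conv") "Wt" else "W"
    for (idx in c(1L, length(net$layers[[li]][[wf]]))) {
      up <- net; up$layers[[li]][[wf]][idx] <- up$layers[[li]][[wf]][idx] + eps
      dn <- net; dn$layers[[li]][[wf]][idx] <- dn$layers[[li]][[wf]][idx] - eps
      num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_equal(g[[li]]$dW[idx], num, tolerance = 1e-4,
                   info = sprintf("layer %d idx %d", li, idx))
    }
  }
})
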